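#' Model configuration for the contact likelihood
#'
#' Collects the tunables of the probabilistic model: the contact radius `r`,
#' the aggregation weight `alpha`, and two numerical floors that keep the
#' log-likelihood finite at spatial clashes and at the saturation point
#' `d2 = sep^2`.
#'
#' `alpha` interpolates the training objective between the per-structure
#' likelihood (`alpha = 0`, consensus / single-cell regime) and the
#' likelihood of the ensemble-mean squared-distance matrix (`alpha = 1`,
#' population / bulk regime).
#'
#' @param r contact radius in lattice-step units (default 1.5).
#' @param alpha aggregation weight in `[0, 1]` (default 0).
#' @param base_floor positive clamp for the attractive-propensity base
#'   (default 1e-12). The base is negative at clashes; the clamp turns those
#'   states into a large but finite penalty.
#' @param d2_floor positive clamp for the squared distance in the
#'   attractive-propensity exponent (default 1, the smallest nonzero squared
#'   inter-bead distance on the unit-step lattice). The exponent is otherwise
#'   infinite when two beads coincide; flooring at the lattice minimum leaves
#'   every non-coincident geometry untouched while capping the coincidence
#'   penalty at `sep^2 * log(base_floor)`, which keeps the objective's
#'   dynamic range within what a derivative-free optimizer can navigate.
#' @param exponent_cap optional cap on the exponent `sep^2 / d2` (default
#'   `Inf`, i.e. off). The uncapped exponent is intended for polymers shorter
#'   than ~150 beads; for longer chains a cap restores clash penalisation at
#'   large separations.
#' @return an object of class `model_config`.
#' @export
model_config <- function(r = 1.5, alpha = 0, base_floor = 1e-12,
                         d2_floor = 1, exponent_cap = Inf) {
  stopifnot(r > 0, alpha >= 0, alpha <= 1, base_floor > 0, d2_floor > 0,
            exponent_cap > 0)
  structure(list(r = r, alpha = alpha, base_floor = base_floor,
                 d2_floor = d2_floor, exponent_cap = exponent_cap),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Contact-likelihood model: r =", x$r, ", alpha =", x$alpha, "\n")
  invisible(x)
}

#' Attractive contact propensity
#'
#' Likelihood factor for a pair labelled as a contact: highest when the
#' squared distance `d2` equals `r^2`, decaying to the floor as `d2`
#' approaches its lattice maximum `sep^2`. Evaluated in log space as
#' `clamp(base, base_floor, 1) ^ (sep^2 / max(d2, d2_floor))` with
#' `base = 1 - |d2 - r^2| / (sep^2 - r^2)`.
#'
#' @param d2 squared Euclidean distance(s), `>= 0`; vectorised.
#' @param sep sequence separation(s) `|i - j|`, integer `>= 2`.
#' @param cfg a [model_config()].
#' @return likelihood factor(s) in `[0, 1]`.
#' @export
attractive_propensity <- function(d2, sep, cfg = model_config()) {
  exp(log_attractive_propensity(d2, sep, cfg))
}

log_attractive_propensity <- function(d2, sep, cfg) {
  if (any(sep <= cfg$r)) {
    stop("separation must exceed the contact radius (nonpositive denominator)",
         call. = FALSE)
  }
  base <- 1 - abs(d2 - cfg$r^2) / (sep^2 - cfg$r^2)
  base <- pmin(pmax(base, cfg$base_floor), 1)
  expo <- pmin(sep^2 / pmax(d2, cfg$d2_floor), cfg$exponent_cap)
  expo * log(base)
}

#' Neutral (non-contact) propensity
#'
#' Logistic likelihood factor for a pair not labelled as a contact: near 1
#' for distances well beyond the contact radius, near 0 within it, exactly
#' 0.5 at `d2 = r^2`. Strictly increasing in `d2`.
#'
#' @inheritParams attractive_propensity
#' @return likelihood factor(s) in `(0, 1)`.
#' @export
neutral_propensity <- function(d2, cfg = model_config()) {
  stats::plogis(4 * (d2 - cfg$r^2))
}

log_neutral_propensity <- function(d2, cfg) {
  stats::plogis(4 * (d2 - cfg$r^2), log.p = TRUE)
}

# ---- pair bookkeeping --------------------------------------------------------

# Eligible pairs are i < j with j - i >= 2; pairs at separation < 2 are never
# scored (adjacent beads are constitutively one step apart). Returns parallel
# vectors of i, j, separation, and the flat upper-triangle position so that
# per-state d2 rows can be stored compactly.
pair_table <- function(N) {
  if (N < 4L) {
    if (N == 3L) return(list(i = 1L, j = 3L, sep = 2L, ut = 2L, n_ut = 3L))
    return(list(i = integer(0), j = integer(0), sep = integer(0),
                ut = integer(0), n_ut = max(0L, N * (N - 1L) %/% 2L)))
  }
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  ut_all <- seq_len(nrow(idx))
  keep <- (idx[, 2L] - idx[, 1L]) >= 2L
  list(i = idx[keep, 1L], j = idx[keep, 2L],
       sep = idx[keep, 2L] - idx[keep, 1L],
       ut = ut_all[keep], n_ut = nrow(idx))
}

# Log-likelihood rows for a states x pairs matrix of squared distances.
# d2_rows: matrix (n_states x n_eligible_pairs); labels: 0/1 per pair.
# Returns a vector of per-state log-likelihoods (constant dropped).
loglik_rows <- function(d2_rows, labels, sep, cfg) {
  d2_rows <- as.matrix(d2_rows)
  n <- nrow(d2_rows)
  if (ncol(d2_rows) == 0L) return(rep(0, n))
  ll <- matrix(0, n, ncol(d2_rows))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  for (k in pos) {
    ll[, k] <- log_attractive_propensity(d2_rows[, k], sep[k], cfg)
  }
  for (k in neg) {
    ll[, k] <- log_neutral_propensity(d2_rows[, k], cfg)
  }
  rowSums(ll)
}

# ---- per-structure and aggregated objectives ---------------------------------

#' Log-likelihood of one structure given a contact map
#'
#' Sum over eligible pairs (`j >= i + 2`) of
#' `pc * log f_plus + (1 - pc) * log f_minus`, with the additive constant
#' dropped; always `<= 0` and finite (the configuration floors guarantee
#' finiteness at clashes).
#'
#' @param d2 `N x N` squared-distance matrix (see
#'   [squared_distance_matrix()]).
#' @param pc a [contact_map()] or plain binary `N x N` matrix.
#' @param cfg a [model_config()].
#' @return scalar log-likelihood `<= 0`.
#' @export
structure_log_likelihood <- function(d2, pc, cfg = model_config()) {
  pc <- unclass(pc)
  if (!all(dim(d2) == dim(pc))) stop("shape mismatch between d2 and pc",
                                     call. = FALSE)
  pt <- pair_table(nrow(d2))
  if (!length(pt$i)) return(0)
  labels <- pc[cbind(pt$i, pt$j)]
  drow <- matrix(d2[cbind(pt$i, pt$j)], nrow = 1L)
  loglik_rows(drow, labels, pt$sep, cfg)
}

#' Aggregated training objective over a sampled ensemble
#'
#' The cost minimised by the variational loop:
#' `-(1 - alpha) * E_k[logL(k)] - alpha * logL(E_k[d2_k])`, where the
#' expectations are count-weighted means over the sampled structures. At
#' `alpha = 0` this is the negated mean per-structure log-likelihood; at
#' `alpha = 1` the negated log-likelihood of the mean squared-distance
#' matrix. All samples enter, clashes included — the likelihood itself
#' penalises them.
#'
#' @param d2_list list of `N x N` squared-distance matrices (one per distinct
#'   sampled structure).
#' @param counts nonnegative weights (shot counts), same length as
#'   `d2_list`, positive total.
#' @param pc a [contact_map()] or binary matrix.
#' @param cfg a [model_config()]; `cfg$alpha` selects the regime.
#' @return scalar objective `>= 0`.
#' @export
aggregated_objective <- function(d2_list, counts, pc, cfg = model_config()) {
  if (!length(d2_list)) stop("empty sample set", call. = FALSE)
  stopifnot(length(counts) == length(d2_list), sum(counts) > 0)
  pc <- unclass(pc)
  N <- nrow(pc)
  pt <- pair_table(N)
  labels <- pc[cbind(pt$i, pt$j)]
  d2_rows <- t(vapply(d2_list, function(m) m[cbind(pt$i, pt$j)],
                      numeric(length(pt$i))))
  if (length(pt$i) == 1L) d2_rows <- matrix(unlist(d2_rows), ncol = 1L)
  w <- counts / sum(counts)
  objective_from_rows(d2_rows, w, labels, pt$sep, cfg)
}

# Shared fast path: d2_rows is states x eligible-pairs, w are normalised
# weights. Used by aggregated_objective, the training loop and the exact
# (probability-weighted) objective.
objective_from_rows <- function(d2_rows, w, labels, sep, cfg) {
  per_state <- loglik_rows(d2_rows, labels, sep, cfg)
  mean_ll <- sum(w * per_state)
  if (cfg$alpha == 0) return(-mean_ll)
  mean_d2 <- as.numeric(crossprod(d2_rows, w))
  pooled_ll <- loglik_rows(matrix(mean_d2, nrow = 1L), labels, sep, cfg)
  -(1 - cfg$alpha) * mean_ll - cfg$alpha * pooled_ll
}
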