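#' Coverage and empirical probability of the low-energy set
#'
#' The "top set" comprises the universe states whose likelihood is at or
#' above the upper `q` quantile of `phi`. Coverage is the fraction of the top
#' set sampled at least once; the empirical probability is the shot-weighted
#' fraction of measurements landing in the top set.
#'
#' @param ens a [conformation_ensemble()].
#' @param phi per-state likelihood vector aligned with the universe
#'   (see [ground_truth_distribution()]).
#' @param q quantile in `[0, 1)`.
#' @return list with `coverage` and `empirical_probability`, both in
#'   `[0, 1]`.
#' @export
coverage_and_empirical_probability <- function(ens, phi, q) {
  threshold <- likelihood_quantile(phi, q)
  top <- which(phi >= threshold)
  if (!length(top)) stop("empty top set", call. = FALSE)
  sampled_rows <- ens$index + 1
  in_top <- sampled_rows %in% top
  list(coverage = sum(in_top) / length(top),
       empirical_probability = sum(ens$count[in_top]) / ens$shots)
}

#' Empirical Shannon entropy of an ensemble
#'
#' Base-2 entropy of the empirical distribution over sampled states; 0 when
#' all shots agree, `log2(k)` for a uniform spread over `k` states.
#'
#' @param ens a [conformation_ensemble()].
#' @return entropy in bits, `>= 0`.
#' @export
empirical_entropy <- function(ens) {
  p <- ens$count / ens$shots
  -sum(p * log2(p))
}

#' Likelihood ratio of the learned distribution by energy level
#'
#' Universe states are ranked by likelihood (highest `phi` = lowest
#' excitation level first) and split into `bins` equal-occupancy bins. Each
#' bin's ratio compares the empirical shot mass it received with the mass a
#' uniform distribution over states would give it; ratios above 1 mark
#' energy levels the sampler favours over random chance.
#'
#' @param ens a [conformation_ensemble()].
#' @param phi per-state likelihood vector aligned with the universe.
#' @param bins number of energy bins, `>= 2` (default 20).
#' @return data frame with one row per bin (lowest energy first): `bin`,
#'   `n_states`, `shot_mass`, `uniform_mass`, `ratio`.
#' @export
likelihood_ratio_by_level <- function(ens, phi, bins = 20L) {
  stopifnot(bins >= 2L)
  n <- length(phi)
  ord <- order(phi, decreasing = TRUE)
  bin_of_rank <- ceiling(seq_len(n) * bins / n)
  state_bin <- integer(n)
  state_bin[ord] <- bin_of_rank
  shot_mass <- vapply(seq_len(bins), function(b) {
    sum(ens$count[state_bin[ens$index + 1] == b]) / ens$shots
  }, numeric(1L))
  n_states <- tabulate(bin_of_rank, bins)
  uniform_mass <- n_states / n
  data.frame(bin = seq_len(bins), n_states = n_states,
             shot_mass = shot_mass, uniform_mass = uniform_mass,
             ratio = shot_mass / uniform_mass)
}

# eligible-pair labels and scores shared by the recovery metrics
recovery_pairs <- function(pc, inferred) {
  pc <- unclass(pc)
  stopifnot(all(dim(pc) == dim(inferred)))
  pt <- pair_table(nrow(pc))
  list(labels = pc[cbind(pt$i, pt$j)], scores = inferred[cbind(pt$i, pt$j)])
}

#' Contact-recovery scores: AUC, AP, and positive-pair summaries
#'
#' Rank-based AUC (tie-averaged) and step-interpolated average precision
#' over the eligible pairs (`j >= i + 2`), with the target contact labels
#' scored by the inferred contact probabilities, plus the mean and maximum
#' inferred probability over the positive pairs.
#'
#' @param pc a [contact_map()] target.
#' @param inferred matrix of inferred contact probabilities (e.g.
#'   [ensemble_mean_inferred()]`$inferred`).
#' @return list with `auc`, `ap`, `mean_pos`, `max_pos`. With single-class
#'   labels `auc` is `NA` with a warning; `ap` is still returned.
#' @export
contact_recovery_scores <- function(pc, inferred) {
  rp <- recovery_pairs(pc, inferred)
  labels <- rp$labels
  scores <- rp$scores
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L) stop("no positive eligible pairs", call. = FALSE)
  auc <- if (n_neg == 0L) {
    warning("AUC undefined for single-class labels")
    NA_real_
  } else {
    r <- rank(scores)  # tie-averaged
    (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  # step-interpolated AP over descending distinct thresholds
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1L))
  fp <- vapply(th, function(t) sum(scores >= t & labels == 0), numeric(1L))
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(auc = auc, ap = ap,
       mean_pos = mean(scores[labels == 1]),
       max_pos = max(scores[labels == 1]))
}

#' Dice-Sorensen indices of contact recovery
#'
#' The weighted index treats the inferred probabilities as soft memberships:
#' `DSI_w = 2 * sum(pc * inferred) / (sum(pc) + sum(inferred))`. The
#' maximum-threshold index binarises the inferred probabilities at every
#' candidate threshold (0 and each distinct inferred value) and takes the
#' best Dice coefficient. Both range over `[0, 1]`; the degenerate all-zero
#' case is defined as 1 (perfect agreement of empty sets), with a message.
#'
#' @inheritParams contact_recovery_scores
#' @return list with `dsi_w` and `dsi_m`.
#' @export
dsi <- function(pc, inferred) {
  rp <- recovery_pairs(pc, inferred)
  labels <- rp$labels
  scores <- rp$scores
  denom_w <- sum(labels) + sum(scores)
  if (denom_w == 0) {
    message("all-zero target and inference; DSI defined as 1 by convention")
    return(list(dsi_w = 1, dsi_m = 1))
  }
  dsi_w <- 2 * sum(labels * scores) / denom_w
  thresholds <- c(0, sort(unique(scores)))
  dice_at <- vapply(thresholds, function(t) {
    ind <- as.numeric(scores > t)
    denom <- sum(labels) + sum(ind)
    if (denom == 0) 1 else 2 * sum(labels * ind) / denom
  }, numeric(1L))
  list(dsi_w = dsi_w, dsi_m = max(dice_at))
}

#' Consensus-structure scores: scale-invariant RMSD and rank correlation
#'
#' The RMSD minimises over a single positive scale factor applied to the
#' model distances, with the closed-form optimum
#' `s* = sum(D * Dt) / sum(D^2)`; the rank correlation is Spearman's rho.
#' Both are computed over the upper-triangle distances (all `i < j`).
#'
#' @param d2 model squared-distance matrix.
#' @param target_d target distance matrix (not squared), positive off the
#'   diagonal.
#' @return list with `rmsd`, `scale` (the optimal `s*`), and `spearman`.
#' @export
consensus_scores <- function(d2, target_d) {
  stopifnot(all(dim(d2) == dim(target_d)))
  ut <- upper.tri(d2)
  D <- sqrt(d2[ut])
  Dt <- target_d[ut]
  if (all(D == 0)) stop("degenerate all-zero model distances", call. = FALSE)
  s <- sum(D * Dt) / sum(D^2)
  list(rmsd = sqrt(mean((s * D - Dt)^2)), scale = s,
       spearman = stats::cor(D, Dt, method = "spearman"))
}

#' Jensen-Shannon divergence between two sampled ensembles
#'
#' Base-2 JS divergence between the empirical distributions of the two
#' ensembles, in `[0, 1]`. By default conformations are first merged by
#' their contact set, so the comparison happens at the level of discrete
#' contact-matrix distributions; `level = "states"` compares raw spin-string
#' distributions. An `embed` hook may replace the distribution construction
#' entirely (it receives both ensembles and must return `list(p, q)` of
#' aligned probability vectors), allowing external density-based variants.
#'
#' @param a,b [conformation_ensemble()]s over the same bead count.
#' @param level `"contacts"` (default) or `"states"`.
#' @param r contact radius used when merging by contact set.
#' @param embed optional function implementing a custom density comparison.
#' @return scalar divergence in `[0, 1]`.
#' @export
ensemble_js_divergence <- function(a, b, level = c("contacts", "states"),
                                   r = 1.5, embed = NULL) {
  if (a$N != b$N) stop("ensembles have different bead counts", call. = FALSE)
  if (!is.null(embed)) {
    d <- embed(a, b)
    return(js_divergence(d$p, d$q))
  }
  level <- match.arg(level)
  key_fun <- switch(level,
    states = function(e) as.character(e$index),
    contacts = function(e) ensemble_contact_keys(e, r))
  ka <- key_fun(a)
  kb <- key_fun(b)
  keys <- union(ka, kb)
  # several states can share one contact set; masses must accumulate
  mass <- function(k, e) {
    agg <- rowsum(e$count / e$shots, k)
    out <- agg[match(keys, rownames(agg)), 1L]
    out[is.na(out)] <- 0
    out
  }
  js_divergence(mass(ka, a), mass(kb, b))
}

# contact-set key per distinct ensemble state ("i-j;i-j", sorted)
ensemble_contact_keys <- function(ens, r = 1.5) {
  N <- ens$N
  d2 <- states_d2_ut(ens$index, N)
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  eligible <- (idx[, 2L] - idx[, 1L]) > r
  lab <- paste0(idx[eligible, 1L], "-", idx[eligible, 2L])
  cmat <- d2[, eligible, drop = FALSE] <= r^2
  apply(cmat, 1L, function(z) paste(lab[z], collapse = ";"))
}

js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Paired F1 matching between two sets of contact matrices
#'
#' Builds the pairwise F1 matrix between the two sets (F1 over the binary
#' upper-triangle entries), solves the rectangular linear-sum-assignment
#' problem maximising total F1 (as a maximum-weight bipartite matching), and
#' reports the matched scores together with the fraction of matches at or
#' above each threshold on a grid. Duplicate matrices in `a` are removed
#' first.
#'
#' @param a,b lists of binary contact matrices (or [contact_map()]s) of
#'   equal dimension.
#' @param thresholds numeric grid for the score-fraction summary.
#' @return list with `scores` (matched F1 values, one per matched pair),
#'   `pairs` (two-column matrix of matched indices into the deduplicated `a`
#'   and into `b`), and `fraction_above` (named vector over `thresholds`).
#' @export
paired_f1 <- function(a, b, thresholds = seq(0, 1, by = 0.1)) {
  stopifnot(length(a) > 0, length(b) > 0)
  vecs_a <- unique(lapply(a, function(m) as.numeric(unclass(m)[upper.tri(m)])))
  vecs_b <- lapply(b, function(m) as.numeric(unclass(m)[upper.tri(m)]))
  na <- length(vecs_a)
  nb <- length(vecs_b)
  f1 <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      f1[i, j] <- binary_f1(vecs_a[[i]], vecs_b[[j]])
    }
  }
  m <- assignment_matching(f1)
  scores <- f1[m]
  list(scores = scores, pairs = m,
       fraction_above = stats::setNames(
         vapply(thresholds, function(t) mean(scores >= t), numeric(1L)),
         format(thresholds)))
}

binary_f1 <- function(x, y) {
  tp <- sum(x == 1 & y == 1)
  fp <- sum(x == 0 & y == 1)
  fn <- sum(x == 1 & y == 0)
  if (tp + fp + fn == 0) return(1)  # two empty contact sets agree perfectly
  2 * tp / (2 * tp + fp + fn)
}

# maximum-weight bipartite matching of a (na x nb) nonnegative score matrix;
# returns a min(na, nb)-row matrix of matched (row, col) indices. A small
# epsilon keeps zero-score pairs matchable so the matching is maximal.
assignment_matching <- function(score) {
  na <- nrow(score)
  nb <- ncol(score)
  edges <- expand.grid(i = seq_len(na), j = seq_len(nb))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(t(cbind(edges$i, na + edges$j))))
  igraph::E(g)$weight <- score[cbind(edges$i, edges$j)] + 1e-9
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  matched <- which(!is.na(mm$matching[seq_len(na)]))
  cbind(a = matched, b = mm$matching[matched] - na)
}
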