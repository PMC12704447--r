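#' Exhaustive enumeration of the conformational universe
#'
#' For a polymer of `N` beads there are exactly `8^(N-2)` spin strings. For
#' small `N` all of them can be decoded, clash-flagged and contact-annotated,
#' giving a ground-truth reference ("universe") against which sampled
#' ensembles are scored. State `k` of the universe (1-based row) corresponds
#' to basis index `k - 1` under the shared bit convention (qubit 0 least
#' significant).
#'
#' Memory grows as `8^(N-2)`; the default cap is `N <= 8` (about 2.6e5
#' states). `N` of 9 or 10 is permitted behind `allow_large = TRUE`.
#'
#' @param N bead count, `2 <= N <= 10`.
#' @param r contact radius (default 1.5).
#' @param allow_large set `TRUE` to enumerate `N > 8`.
#' @return an object of class `structure_universe` with elements `N`, `r`,
#'   `num_qubits`, `n_states`, `d2` (states-by-pairs matrix of squared
#'   distances over all `i < j`, flat upper-triangle order), `clash_free`
#'   (logical per state), `contact_key` (canonical "i-j;i-j" string per
#'   state), and the pair table `pt`.
#' @export
enumerate_universe <- function(N, r = 1.5, allow_large = FALSE) {
  stopifnot(N >= 2L, N == round(N))
  cap <- if (allow_large) 10L else 8L
  if (N > cap) {
    stop("N = ", N, " exceeds the enumeration cap (", cap, "); ",
         "use allow_large = TRUE for N up to 10", call. = FALSE)
  }
  nq <- 3L * (N - 2L)
  n_states <- 8^(N - 2L)
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  n_ut <- nrow(idx)
  sep_ut <- idx[, 2L] - idx[, 1L]

  d2 <- matrix(0, n_states, max(n_ut, 1L))
  clash_free <- logical(n_states)
  keys <- character(n_states)
  eligible <- sep_ut > r  # pairs that can ever be contacts

  lab <- paste0(idx[eligible, 1L], "-", idx[eligible, 2L])
  chunk <- 65536L
  starts <- seq(0, n_states - 1L, by = chunk)
  for (s0 in starts) {
    rows <- (s0 + 1L):min(s0 + chunk, n_states)
    if (n_ut > 0L) {
      dsub <- states_d2_ut(rows - 1L, N)
      d2[rows, ] <- dsub
      clash_free[rows] <- rowSums(dsub < 0.0625) == 0L  # (1/4)^2
      cmat <- dsub[, eligible, drop = FALSE] <= r^2
      keys[rows] <- apply(cmat, 1L, function(z) paste(lab[z], collapse = ";"))
    } else {
      clash_free[rows] <- TRUE
      keys[rows] <- ""
    }
  }

  structure(list(N = N, r = r, num_qubits = nq, n_states = n_states,
                 d2 = d2, clash_free = clash_free, contact_key = keys,
                 ut_i = idx[, 1L], ut_j = idx[, 2L], sep_ut = sep_ut,
                 pt = pair_table(N)),
            class = "structure_universe")
}

#' @export
print.structure_universe <- function(x, ...) {
  cat("Structure universe: N =", x$N, "(", x$n_states, "states,",
      sum(x$clash_free), "clash-free )\n")
  invisible(x)
}

#' Full squared-distance matrix of one universe state
#'
#' @param u a [enumerate_universe()] result.
#' @param state 1-based state row (basis index + 1).
#' @return symmetric `N x N` squared-distance matrix.
#' @export
universe_d2_matrix <- function(u, state) {
  m <- matrix(0, u$N, u$N)
  m[cbind(u$ut_i, u$ut_j)] <- u$d2[state, ]
  m + t(m)
}

# d2 rows restricted to the eligible (scored) pairs, aligned with pair_table
universe_eligible_d2 <- function(u, states = seq_len(u$n_states)) {
  u$d2[states, u$pt$ut, drop = FALSE]
}

#' Partition the clash-free universe into contact groups
#'
#' Clash-free states sharing the same contact set form a group; groups are
#' disjoint and jointly cover every clash-free state. Each group's contact
#' set, materialised as a binary matrix, defines one simulated Hi-C target.
#'
#' @param u a [enumerate_universe()] result.
#' @return named list of `target_group` objects, keyed by the canonical
#'   contact-set string; each has `key`, `chi` (two-column pair matrix),
#'   `members` (1-based state rows), `contact_map`, and `N`.
#' @export
partition_groups <- function(u) {
  cf <- which(u$clash_free)
  split_members <- split(cf, u$contact_key[cf])
  out <- lapply(seq_along(split_members), function(k) {
    key <- names(split_members)[k]
    chi <- key_to_pairs(key)
    structure(list(key = key, chi = chi,
                   members = split_members[[k]],
                   contact_map = contact_map_from_pairs(chi, u$N),
                   N = u$N),
              class = "target_group")
  })
  names(out) <- names(split_members)
  out
}

key_to_pairs <- function(key) {
  if (!nzchar(key)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- t(vapply(parts, as.integer, integer(2L)))
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

#' @export
print.target_group <- function(x, ...) {
  cat("Target group: N =", x$N, ",", nrow(x$chi), "contacts,",
      length(x$members), "member structures\n")
  invisible(x)
}

#' Draw a simulated Hi-C target uniformly over contact groups
#'
#' @param u a [enumerate_universe()] result.
#' @param seed integer seed; the same seed always yields the same group.
#' @return a `target_group` (see [partition_groups()]).
#' @export
sample_target <- function(u, seed = NULL) {
  groups <- partition_groups(u)
  pick <- with_seed(seed, sample.int(length(groups), 1L))
  groups[[pick]]
}

#' Ground-truth likelihood distribution over the universe
#'
#' Evaluates the structure likelihood of every enumerable state under a
#' target contact map. Higher likelihood corresponds to a lower excitation
#' (energy) level; the maximum-likelihood states are the ground states.
#'
#' @param u a [enumerate_universe()] result.
#' @param pc a [contact_map()] with `N` matching the universe.
#' @param cfg a [model_config()].
#' @return list with `log_phi` (per-state log-likelihood), `phi`
#'   (`exp(log_phi)`), and `prob` (`phi` normalised to sum 1).
#' @export
ground_truth_distribution <- function(u, pc, cfg = model_config()) {
  pc <- unclass(pc)
  stopifnot(nrow(pc) == u$N)
  pt <- u$pt
  labels <- pc[cbind(pt$i, pt$j)]
  log_phi <- loglik_rows(universe_eligible_d2(u), labels, pt$sep, cfg)
  phi <- exp(log_phi)
  list(log_phi = log_phi, phi = phi, prob = phi / sum(phi))
}

#' Upper-quantile threshold of a likelihood vector
#'
#' Linear-interpolation empirical quantile; states with `phi >=` the
#' returned threshold form the "top" (low-energy) set, ties included.
#'
#' @param phi nonempty numeric vector of likelihood values.
#' @param q quantile in `[0, 1)`.
#' @return scalar threshold.
#' @export
likelihood_quantile <- function(phi, q) {
  if (!length(phi)) stop("phi is empty", call. = FALSE)
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)", call. = FALSE)
  unname(stats::quantile(phi, q, type = 7L))
}

# Run an expression under a temporary RNG state. With a NULL seed the global
# RNG is used (and advanced) as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
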