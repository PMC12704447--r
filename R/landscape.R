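#' Empirical maximum information content of the objective landscape
#'
#' A landscape-ruggedness statistic from symbolised cost differences along
#' random walks in parameter space. `128 * p` uniform parameter points
#' normalise the cost scale; `64` random walks of `64 * p` steps each are
#' then taken, consecutive cost differences are symbolised into
#' `{-1, 0, +1}` with respect to a sensitivity `eps`, and the information
#' content `H(eps) = -sum_{a != b} p_ab log6 p_ab` is computed over
#' consecutive symbol pairs. The maximum of the walk-averaged `H(eps)` over
#' an `eps` grid spanning the observed difference magnitudes is returned.
#' Higher values indicate a more rugged (and typically more trainable)
#' landscape.
#'
#' @param objective function of a length-`p` parameter vector returning a
#'   scalar cost (e.g. [exact_objective()]).
#' @param p parameter count, `>= 1`.
#' @param seed optional integer seed.
#' @param n_samples uniform points for scale normalisation (default
#'   `128 * p`).
#' @param n_walks number of random walks (default 64).
#' @param walk_length cost evaluations per walk (default `64 * p`).
#' @param step per-coordinate half-width of one uniform walk step, radians
#'   (default 0.1).
#' @param n_eps size of the sensitivity grid (default 24).
#' @return list with `H_M` (the maximum information content, in `[0, 1]`)
#'   and `profile` (data frame of `eps` versus walk-averaged `H`).
#' @export
landscape_mic <- function(objective, p, seed = NULL, n_samples = 128L * p,
                          n_walks = 64L, walk_length = 64L * p, step = 0.1,
                          n_eps = 24L) {
  if (p < 1L) stop("p must be at least 1", call. = FALSE)
  with_seed(seed, {
    sample_costs <- vapply(seq_len(n_samples),
                           function(k) objective(stats::runif(p, 0, 2 * pi)),
                           numeric(1L))
    scale <- diff(range(sample_costs))
    diffs <- vector("list", n_walks)
    for (w in seq_len(n_walks)) {
      theta <- stats::runif(p, 0, 2 * pi)
      costs <- numeric(walk_length)
      costs[1L] <- objective(theta)
      for (t in 2L:walk_length) {
        theta <- (theta + stats::runif(p, -step, step)) %% (2 * pi)
        costs[t] <- objective(theta)
      }
      diffs[[w]] <- diff(costs)
    }
    if (scale == 0) {
      return(list(H_M = 0,
                  profile = data.frame(eps = 0, H = 0)))
    }
    diffs <- lapply(diffs, function(d) d / scale)
    mags <- abs(unlist(diffs))
    pos <- mags[mags > 0]
    eps_grid <- if (length(pos)) {
      c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = n_eps)))
    } else {
      0
    }
    H <- vapply(eps_grid, function(eps) {
      mean(vapply(diffs, walk_information_content, numeric(1L), eps = eps))
    }, numeric(1L))
    list(H_M = max(H), profile = data.frame(eps = eps_grid, H = H))
  })
}

# information content of one walk's difference sequence at sensitivity eps:
# symbols in {-1, 0, +1}, probabilities of the six unequal consecutive symbol
# pairs over all consecutive pairs, entropy in base 6 so H is in [0, 1].
walk_information_content <- function(d, eps) {
  s <- sign(d) * (abs(d) > eps)
  a <- s[-length(s)]
  b <- s[-1L]
  uneq <- a != b
  if (!any(uneq)) return(0)
  pair_counts <- table(paste(a[uneq], b[uneq]))
  p_ab <- as.numeric(pair_counts) / length(a)
  -sum(p_ab * log(p_ab, base = 6))
}
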