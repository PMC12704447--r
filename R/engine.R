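#' Ensembles of measured conformations
#'
#' An ensemble records the multiset of spin strings obtained from `shots`
#' measurements of the circuit: distinct basis-state indices with their shot
#' counts. Indices follow the shared convention (qubit 0 = bead 3's x spin =
#' least significant bit).
#'
#' @param index numeric vector of distinct basis-state indices (0-based).
#' @param count positive integer shot counts, same length as `index`.
#' @param num_qubits number of qubits.
#' @return an object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(index, count, num_qubits) {
  stopifnot(length(index) == length(count), all(count > 0),
            all(index >= 0), all(index < 2^num_qubits),
            !anyDuplicated(index))
  structure(list(index = as.numeric(index), count = as.numeric(count),
                 shots = sum(count), num_qubits = as.integer(num_qubits),
                 N = as.integer(num_qubits / 3L + 2L)),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("Conformation ensemble:", x$shots, "shots over", length(x$index),
      "distinct states (N =", x$N, ")\n")
  invisible(x)
}

#' @export
as.data.frame.conformation_ensemble <- function(x, ...) {
  bs <- vapply(x$index,
               function(i) spins_to_bitstring(index_to_spins(i, x$num_qubits)),
               character(1L))
  data.frame(index = x$index, bitstring = bs, count = x$count,
             frequency = x$count / x$shots)
}

#' Sample shot measurements from a probability vector
#'
#' Multinomial draw of `shots` measurements over the `2^num_qubits` basis
#' states. Statistically identical to per-shot circuit execution, at
#' desk-scale speed.
#'
#' @param probabilities probability vector over basis states (sums to 1).
#' @param shots number of measurements, `>= 1` (default 4096).
#' @param seed optional integer seed for reproducible draws.
#' @return a [conformation_ensemble()].
#' @export
sample_measurements <- function(probabilities, shots = 4096L, seed = NULL) {
  if (shots < 1L) stop("shots must be at least 1", call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-8 || any(probabilities < 0)) {
    stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  nq <- as.integer(round(log2(length(probabilities))))
  cnt <- with_seed(seed, stats::rmultinom(1L, shots, probabilities))[, 1L]
  nz <- which(cnt > 0L)
  conformation_ensemble(nz - 1, cnt[nz], nq)
}

#' Prepare and sample the trained state
#'
#' Composition of [simulate_probabilities()] and [sample_measurements()].
#'
#' @inheritParams simulate_amplitudes
#' @inheritParams sample_measurements
#' @return a [conformation_ensemble()].
#' @export
sample_ensemble <- function(ansatz, theta, shots = 4096L, seed = NULL) {
  if (ansatz$num_qubits == 0L) {
    # degenerate two-bead polymer: single fixed conformation, no circuit
    return(conformation_ensemble(0, shots, 0L))
  }
  sample_measurements(simulate_probabilities(ansatz, theta), shots, seed)
}

# ---- structure cache ---------------------------------------------------------

# Memoises, per (pc, cfg), the scored squared-distance rows and per-structure
# log-likelihood of every basis state seen so far, so repeated optimizer
# evaluations never re-decode a state. Returns an object with $fetch(indices),
# $labels, $sep.
make_state_cache <- function(N, pc, cfg) {
  pt <- pair_table(N)
  labels <- unclass(pc)[cbind(pt$i, pt$j)]
  nq <- 3L * (N - 2L)
  use_vec <- nq <= 20L
  lookup <- if (use_vec) integer(2^nq) else new.env(parent = emptyenv())
  rows <- matrix(0, 0L, length(pt$i))
  ll <- numeric(0)
  fetch <- function(indices) {
    pos <- if (use_vec) {
      lookup[indices + 1L]
    } else {
      vapply(as.character(indices),
             function(k) if (is.null(lookup[[k]])) 0L else lookup[[k]],
             integer(1L), USE.NAMES = FALSE)
    }
    miss <- which(pos == 0L)
    if (length(miss)) {
      d2new <- states_d2_ut(indices[miss], N)[, pt$ut, drop = FALSE]
      llnew <- loglik_rows(d2new, labels, pt$sep, cfg)
      newpos <- nrow(rows) + seq_along(miss)
      rows <<- rbind(rows, d2new)
      ll <<- c(ll, llnew)
      if (use_vec) {
        lookup[indices[miss] + 1L] <<- newpos
      } else {
        for (k in seq_along(miss)) {
          lookup[[as.character(indices[miss[k]])]] <- newpos[k]
        }
      }
      pos[miss] <- newpos
    }
    list(d2 = rows[pos, , drop = FALSE], loglik = ll[pos])
  }
  list(fetch = fetch, labels = labels, sep = pt$sep)
}

# ---- objectives --------------------------------------------------------------

#' Shot-based and exact training objectives
#'
#' `shot_objective()` returns a closure `f(theta)` that prepares the state,
#' draws `shots` measurements and evaluates the aggregated objective over the
#' sampled structures — the quantity minimised during training.
#' `exact_objective()` instead weights every enumerable structure by its
#' exact measurement probability, giving the deterministic infinite-shot
#' limit; it is the reference the statevector expectation is checked against
#' and the function used for landscape analysis.
#'
#' @param pc a [contact_map()].
#' @param cfg a [model_config()].
#' @param ansatz an [build_ansatz()]; defaults to the two-repetition ansatz
#'   for `nrow(pc)` beads.
#' @param shots measurements per evaluation (default 4096).
#' @param seed optional integer seed; evaluation `k` of the returned closure
#'   draws its shots from a stream derived deterministically from it.
#' @param universe optional pre-enumerated [enumerate_universe()] (exact
#'   objective only); enumerated on demand otherwise.
#' @return a function `f(theta)` returning the scalar objective.
#' @export
shot_objective <- function(pc, cfg = model_config(),
                           ansatz = build_ansatz(nrow(pc)),
                           shots = 4096L, seed = NULL) {
  N <- nrow(pc)
  cache <- make_state_cache(N, pc, cfg)
  eval_seeds <- if (is.null(seed)) NULL else
    with_seed(seed, sample.int(.Machine$integer.max, 100000L))
  k <- 0L
  function(theta) {
    k <<- k + 1L
    probs <- simulate_probabilities(ansatz, theta)
    s <- if (is.null(eval_seeds)) NULL else eval_seeds[k]
    ens <- sample_measurements(probs, shots, s)
    st <- cache$fetch(ens$index)
    objective_from_rows(st$d2, ens$count / ens$shots, cache$labels, cache$sep,
                        cfg)
  }
}

#' @rdname shot_objective
#' @export
exact_objective <- function(pc, cfg = model_config(),
                            ansatz = build_ansatz(nrow(pc)),
                            universe = NULL) {
  N <- nrow(pc)
  if (is.null(universe)) universe <- enumerate_universe(N, r = cfg$r)
  stopifnot(universe$N == N)
  pt <- universe$pt
  labels <- unclass(pc)[cbind(pt$i, pt$j)]
  d2_rows <- universe_eligible_d2(universe)
  ll <- loglik_rows(d2_rows, labels, pt$sep, cfg)
  function(theta) {
    probs <- simulate_probabilities(ansatz, theta)
    mean_ll <- sum(probs * ll)
    if (cfg$alpha == 0) return(-mean_ll)
    mean_d2 <- as.numeric(crossprod(d2_rows, probs))
    pooled <- loglik_rows(matrix(mean_d2, 1L), labels, pt$sep, cfg)
    -(1 - cfg$alpha) * mean_ll - cfg$alpha * pooled
  }
}

# ---- training ----------------------------------------------------------------

#' Training configuration
#'
#' @param shots measurements per objective evaluation (default 4096).
#' @param seed integer seed governing parameter initialisation and every
#'   shot draw; `NULL` uses the session RNG.
#' @param max_evals objective-evaluation budget (default 1000).
#' @param initial_step initial trust-region step of the optimizer, radians
#'   (default 0.7).
#' @param xtol_rel relative parameter tolerance for convergence
#'   (default 1e-3).
#' @return an object of class `train_config`.
#' @export
train_config <- function(shots = 4096L, seed = NULL, max_evals = 1000L,
                         initial_step = 0.7, xtol_rel = 1e-3) {
  stopifnot(shots >= 1L, max_evals >= 1L, initial_step > 0, xtol_rel > 0)
  structure(list(shots = as.integer(shots), seed = seed,
                 max_evals = as.integer(max_evals),
                 initial_step = initial_step, xtol_rel = xtol_rel),
            class = "train_config")
}

#' Train the variational sampler on a contact map
#'
#' The variational loop: prepare `|psi(theta)>`, draw `shots` measurements,
#' decode them to lattice structures, evaluate the aggregated contact
#' likelihood objective, and let COBYLA (derivative-free linear
#' approximation) update `theta`. Parameters are initialised uniformly over
#' `[0, 2*pi)`. The returned parameters are the best seen over the whole
#' trace, not the last iterate.
#'
#' @param pc a [contact_map()] target.
#' @param cfg a [model_config()]; `cfg$alpha` selects consensus
#'   (`alpha = 0`) versus population (`alpha = 1`) modelling.
#' @param tcfg a [train_config()].
#' @param ansatz optional [build_ansatz()] override.
#' @return an object of class `vqa_fit`: `theta_star`, `best_cost`,
#'   `cost_trace`, `n_evals`, `seed`, plus the configurations used.
#' @export
train_model <- function(pc, cfg = model_config(), tcfg = train_config(),
                        ansatz = NULL) {
  N <- nrow(pc)
  if (is.null(ansatz)) ansatz <- build_ansatz(N)
  stopifnot(ansatz$N == N)
  p <- ansatz$n_params
  if (p == 0L) {
    return(structure(list(theta_star = numeric(0), best_cost = 0,
                          cost_trace = numeric(0), n_evals = 0L,
                          seed = tcfg$seed, ansatz = ansatz, cfg = cfg,
                          tcfg = tcfg, message = "degenerate two-bead polymer"),
                     class = "vqa_fit"))
  }
  init_seed <- if (is.null(tcfg$seed)) NULL else
    with_seed(tcfg$seed, sample.int(.Machine$integer.max, 2L))
  theta0 <- with_seed(if (is.null(init_seed)) NULL else init_seed[1L],
                      stats::runif(p, 0, 2 * pi))
  objective <- shot_objective(pc, cfg, ansatz, tcfg$shots,
                              if (is.null(init_seed)) NULL else init_seed[2L])
  trace <- numeric(0)
  best <- Inf
  best_theta <- theta0
  wrapped <- function(theta) {
    val <- objective(theta)
    if (!is.finite(val)) {
      stop("non-finite objective at evaluation ", length(trace) + 1L,
           call. = FALSE)
    }
    trace[length(trace) + 1L] <<- val
    if (val < best) {
      best <<- val
      best_theta <<- theta
    }
    val
  }
  res <- nloptr::cobyla(theta0, wrapped,
                        control = list(maxeval = tcfg$max_evals,
                                       xtol_rel = tcfg$xtol_rel,
                                       initial_step = tcfg$initial_step))
  structure(list(theta_star = best_theta, best_cost = best,
                 cost_trace = trace, n_evals = length(trace),
                 seed = tcfg$seed, ansatz = ansatz, cfg = cfg, tcfg = tcfg,
                 message = res$message),
            class = "vqa_fit")
}

#' @export
print.vqa_fit <- function(x, ...) {
  cat("Variational fit: N =", x$ansatz$N, ", alpha =", x$cfg$alpha,
      "\n  best cost", format(x$best_cost, digits = 6L), "after", x$n_evals,
      "evaluations\n")
  invisible(x)
}

#' @export
as.data.frame.vqa_fit <- function(x, ...) {
  data.frame(eval = seq_along(x$cost_trace), cost = x$cost_trace)
}

#' @export
plot.vqa_fit <- function(x, ...) {
  graphics::plot(seq_along(x$cost_trace), x$cost_trace, type = "l",
                 log = if (all(x$cost_trace > 0)) "y" else "",
                 xlab = "objective evaluation", ylab = "cost",
                 main = sprintf("Variational fit (N = %d, alpha = %g)",
                                x$ansatz$N, x$cfg$alpha), ...)
  graphics::abline(h = x$best_cost, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
summary.vqa_fit <- function(object, ...) {
  cat("Variational fit summary\n")
  cat("  beads:", object$ansatz$N, " qubits:", object$ansatz$num_qubits,
      " parameters:", object$ansatz$n_params, "\n")
  cat("  alpha:", object$cfg$alpha, " shots:", object$tcfg$shots, "\n")
  cat("  evaluations:", object$n_evals, " best cost:",
      format(object$best_cost, digits = 8L), "\n")
  invisible(object)
}

# ---- serialization -----------------------------------------------------------

#' Serialize fits and ensembles as JSON
#'
#' A fit is stored as `{theta, cost_trace, best_cost, seed}`; an ensemble as
#' a `{bitstring: count}` map (first bitstring character = qubit 0).
#'
#' @param fit a `vqa_fit`.
#' @param path file path.
#' @return `path` invisibly; readers return the reconstructed object.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(N = fit$ansatz$N, reps = fit$ansatz$reps,
                            alpha = fit$cfg$alpha,
                            theta = fit$theta_star,
                            cost_trace = fit$cost_trace,
                            best_cost = fit$best_cost,
                            seed = fit$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @param ens a [conformation_ensemble()].
#' @export
write_ensemble <- function(ens, path) {
  df <- as.data.frame(ens)
  counts <- as.list(stats::setNames(df$count, df$bitstring))
  jsonlite::write_json(counts, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_ensemble <- function(path) {
  counts <- jsonlite::read_json(path, simplifyVector = TRUE)
  nq <- nchar(names(counts)[1L])
  idx <- vapply(names(counts),
                function(b) spins_to_index(bitstring_to_spins(b)), numeric(1L),
                USE.NAMES = FALSE)
  ord <- order(idx)
  conformation_ensemble(idx[ord], as.numeric(counts)[ord], nq)
}
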