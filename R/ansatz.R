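#' Build the real-amplitude ansatz specification
#'
#' The generative circuit for an `N`-bead polymer acts on `3(N-2)` qubits:
#' one y-rotation layer, then `reps` blocks of a reverse-linear chain of
#' controlled-NOT couplings followed by another y-rotation layer. With the
#' default two repetitions the parameter count is `(reps + 1) * 3(N-2) =
#' 9(N-2)`. All gates are real, so the prepared amplitudes are real and the
#' measurement distribution over bitstrings is their square.
#'
#' @param N bead count, `N >= 2` (`N = 2` is the degenerate zero-qubit
#'   circuit preparing the single fixed conformation).
#' @param reps number of entangling repetitions (default 2).
#' @return an object of class `ansatz` with `N`, `num_qubits`, `reps`,
#'   `n_params`, and `entangler` (the ordered control/target pairs of one
#'   entangling block, 0-based qubit labels).
#' @examples
#' build_ansatz(6)   # 12 qubits, 36 parameters
#' @export
build_ansatz <- function(N, reps = 2L) {
  stopifnot(N >= 2L, N == round(N))
  if (reps < 1L) stop("reps must be at least 1", call. = FALSE)
  nq <- 3L * (N - 2L)
  ent <- if (nq >= 2L) {
    cbind(control = (nq - 2L):0L, target = (nq - 1L):1L)
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("control", "target")))
  }
  structure(list(N = as.integer(N), num_qubits = nq, reps = as.integer(reps),
                 n_params = (reps + 1L) * nq, entangler = ent),
            class = "ansatz")
}

#' @export
print.ansatz <- function(x, ...) {
  cat("Real-amplitude ansatz: N =", x$N, "->", x$num_qubits, "qubits,",
      x$reps, "repetitions,", x$n_params, "parameters\n")
  invisible(x)
}

#' Simulate the prepared state of the ansatz
#'
#' Exact statevector simulation. `simulate_amplitudes()` returns the real
#' amplitude vector over the `2^num_qubits` basis states (qubit 0 least
#' significant); `simulate_probabilities()` returns its elementwise square,
#' which sums to 1.
#'
#' @param ansatz an [build_ansatz()] specification.
#' @param theta numeric parameter vector of length `ansatz$n_params`
#'   (layer-major: the first `num_qubits` entries are the first rotation
#'   layer).
#' @return numeric vector of length `2^num_qubits`.
#' @export
simulate_amplitudes <- function(ansatz, theta) {
  if (length(theta) != ansatz$n_params) {
    stop("theta must have length ", ansatz$n_params, " (got ", length(theta),
         ")", call. = FALSE)
  }
  real_amplitudes_state(ansatz$num_qubits, as.numeric(theta), ansatz$reps)
}

#' @rdname simulate_amplitudes
#' @export
simulate_probabilities <- function(ansatz, theta) {
  simulate_amplitudes(ansatz, theta)^2
}
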