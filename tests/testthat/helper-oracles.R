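# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms/code paths than the package.

# -- brute-force lattice enumeration (loop-based, dist()-based) ---------------
# Enumerates all 8^(N-2) spin strings via expand.grid, decodes each with an
# explicit per-bead loop, and classifies clashes/contacts with base dist().
oracle_enumerate <- function(N, r = 1.5) {
  n_spins <- 3 * (N - 2)
  grids <- rep(list(c(-1, 1)), n_spins)
  spin_rows <- if (n_spins > 0) as.matrix(expand.grid(grids)) else
    matrix(numeric(0), nrow = 1, ncol = 0)
  out <- vector("list", nrow(spin_rows))
  for (k in seq_len(nrow(spin_rows))) {
    spins <- as.numeric(spin_rows[k, ])
    coords <- matrix(0, N, 3)
    coords[2, ] <- c(1, 1, 1) / sqrt(3)
    if (N > 2) {
      for (b in 3:N) {
        step <- spins[(3 * (b - 3) + 1):(3 * (b - 3) + 3)] / sqrt(3)
        coords[b, ] <- coords[b - 1, ] + step
      }
    }
    dm <- as.matrix(dist(coords))
    pairs <- which(upper.tri(dm), arr.ind = TRUE)
    sep <- pairs[, 2] - pairs[, 1]
    in_contact <- dm[pairs] <= r & sep > r
    contacts <- pairs[in_contact, , drop = FALSE]
    key <- paste(sprintf("%d-%d", contacts[, 1], contacts[, 2]),
                 collapse = ";")
    out[[k]] <- list(spins = spins,
                     clash_free = all(dm[upper.tri(dm)] >= 0.25),
                     key = key)
  }
  out
}

# -- dense matrix-product statevector oracle ----------------------------------
# Builds every gate as a full 2^n x 2^n matrix via Kronecker products and
# multiplies them out, qubit 0 least significant.
oracle_ry_gate <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2)
}

oracle_gate_on <- function(U, q, n) {
  M <- 1
  for (k in (n - 1):0) M <- kronecker(M, if (k == q) U else diag(2))
  M
}

oracle_cnot_on <- function(control, target, n) {
  dim <- 2^n
  M <- matrix(0, dim, dim)
  for (i in 0:(dim - 1)) {
    j <- if (bitwAnd(i, 2^control) > 0) bitwXor(i, 2^target) else i
    M[j + 1, i + 1] <- 1
  }
  M
}

oracle_real_amplitudes <- function(n, theta, reps = 2) {
  psi <- c(1, rep(0, 2^n - 1))
  par <- 1
  for (q in 0:(n - 1)) {
    psi <- oracle_gate_on(oracle_ry_gate(theta[par]), q, n) %*% psi
    par <- par + 1
  }
  for (rr in seq_len(reps)) {
    for (cc in (n - 2):0) psi <- oracle_cnot_on(cc, cc + 1, n) %*% psi
    for (q in 0:(n - 1)) {
      psi <- oracle_gate_on(oracle_ry_gate(theta[par]), q, n) %*% psi
      par <- par + 1
    }
  }
  as.numeric(psi)
}

# -- exhaustive linear-sum-assignment oracle ----------------------------------
# Maximum total score over all injections of rows into columns (small sizes).
oracle_assignment <- function(score) {
  na <- nrow(score)
  nb <- ncol(score)
  stopifnot(na <= nb, na <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  best_assign <- NULL
  for (cols in utils::combn(nb, na, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(score[cbind(seq_len(na), p)])
      if (tot > best) {
        best <- tot
        best_assign <- p
      }
    }
  }
  list(total = best, cols = best_assign)
}

# -- convenience: an ensemble with given indices/counts -----------------------
make_ens <- function(index, count, num_qubits) {
  conformation_ensemble(index, count, num_qubits)
}
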