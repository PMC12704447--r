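#' Cubic-lattice encoding of polymer conformations
#'
#' A polymer of `N` beads is threaded through a cubic lattice: beads 1 and 2
#' are fixed at the origin and at `(1,1,1)/sqrt(3)`, and every subsequent bead
#' sits at one of the eight corners of a unit cube centred on its predecessor.
#' Each free bead therefore contributes three spin variables (one per axis,
#' each in `{-1, +1}`), so a conformation of `N` beads is a spin string of
#' length `3(N-2)`. Every lattice step has Euclidean norm 1.
#'
#' Spin ordering is bead-major then axis: positions `1:3` of the string are
#' the x, y, z spins of bead 3 (the first free bead), positions `4:6` those
#' of bead 4, and so on. Under the bit map `0 <-> -1`, `1 <-> +1` the string
#' is bijective with a bitstring whose first character is qubit 0 (the least
#' significant bit of the basis-state index).
#'
#' @name lattice
NULL

#' Validate a spin string
#'
#' @param spins numeric vector of `+1`/`-1` values, length `3(N-2)`.
#' @return the spins, invisibly, after validation.
#' @keywords internal
validate_spins <- function(spins) {
  if (length(spins) %% 3L != 0L) {
    stop("spin string length must be a multiple of 3 (got ", length(spins), ")",
         call. = FALSE)
  }
  if (length(spins) && !all(spins %in% c(-1, 1))) {
    stop("spin values must be -1 or +1", call. = FALSE)
  }
  invisible(spins)
}

#' Decode a spin string into lattice coordinates
#'
#' Beads 1 and 2 are fixed at the origin and at `(1,1,1)/sqrt(3)`; bead
#' `i > 2` is the prefix sum of its predecessors' unit steps, each step being
#' `(z_x, z_y, z_z)/sqrt(3)` for that bead's spin triple.
#'
#' @param spins spin string of length `3(N-2)` with entries in `{-1, +1}`.
#'   The empty vector decodes the degenerate two-bead polymer.
#' @return a `conformation`: an `N x 3` numeric matrix of coordinates (units
#'   of one lattice step) with the originating spins stored as an attribute.
#' @examples
#' decode_spins(c(1, 1, 1))       # 3 beads, third at (2,2,2)/sqrt(3)
#' decode_spins(numeric(0))       # the two fixed beads
#' @export
decode_spins <- function(spins) {
  validate_spins(spins)
  n_free <- length(spins) %/% 3L
  N <- n_free + 2L
  steps <- matrix(0, nrow = N - 1L, ncol = 3L)
  steps[1L, ] <- c(1, 1, 1)
  if (n_free > 0L) {
    steps[-1L, ] <- matrix(spins, ncol = 3L, byrow = TRUE)
  }
  coords <- rbind(0, apply(steps, 2L, cumsum)) / sqrt(3)
  if (N == 2L) coords <- matrix(coords, ncol = 3L)  # apply() drops dims at N=2
  dimnames(coords) <- NULL
  structure(coords, class = "conformation", spins = as.numeric(spins))
}

#' @export
print.conformation <- function(x, ...) {
  cat("Lattice conformation:", nrow(x), "beads\n")
  print(round(unclass(x), 4L))
  invisible(x)
}

#' Re-encode a conformation as its spin string
#'
#' The inverse of [decode_spins()]: signs of consecutive coordinate
#' differences times `sqrt(3)`. Only differences of free beads (bead 3
#' onward) enter the string.
#'
#' @param conf a `conformation` or plain `N x 3` coordinate matrix on the
#'   lattice.
#' @return numeric spin vector of length `3(N-2)`.
#' @export
encode_conformation <- function(conf) {
  coords <- unclass(conf)
  N <- nrow(coords)
  if (N <= 2L) return(numeric(0))
  d <- diff(coords)[-1L, , drop = FALSE] * sqrt(3)
  spins <- sign(round(d))
  if (any(spins == 0)) stop("coordinates are not on the lattice", call. = FALSE)
  as.numeric(t(spins))
}

#' Squared Euclidean distance matrix of a conformation
#'
#' By construction of the unit-step lattice, `d2[i, j] <= (i - j)^2`.
#'
#' @param conf a `conformation` or `N x 3` coordinate matrix.
#' @return symmetric `N x N` matrix of squared distances, zero diagonal.
#' @export
squared_distance_matrix <- function(conf) {
  coords <- unclass(conf)
  g <- tcrossprod(coords)
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Contact set of a conformation
#'
#' Beads `i < j` are in contact when their Euclidean distance is at most the
#' contact radius `r` and their sequence separation exceeds `r` (with the
#' default radius of 1.5 this requires `|i - j| >= 2`). Adjacent beads are always
#' one step apart and are never scored as contacts.
#'
#' @param conf a `conformation` or coordinate matrix.
#' @param r contact radius in lattice-step units (default 1.5).
#' @return integer matrix with columns `i`, `j` (1-based bead indices,
#'   `i < j`), zero rows when no contact exists.
#' @export
contact_set <- function(conf, r = 1.5) {
  stopifnot(r > 0)
  d2 <- squared_distance_matrix(conf)
  N <- nrow(d2)
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  if (N < 2L) return(out)
  idx <- which(upper.tri(d2), arr.ind = TRUE)
  sep <- idx[, 2L] - idx[, 1L]
  keep <- sep > r & d2[idx] <= r^2
  out <- idx[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Is a conformation free of spatial clashes?
#'
#' A clash is any pair of beads closer than `min_dist`. On this lattice all
#' nonzero inter-bead distances are at least 1, so with the default threshold
#' of 1/4 the test reduces to "no two beads coincide".
#'
#' @param conf a `conformation` or coordinate matrix.
#' @param min_dist minimum allowed pairwise distance (default 0.25).
#' @return logical flag.
#' @export
is_clash_free <- function(conf, min_dist = 0.25) {
  stopifnot(min_dist > 0)
  d2 <- squared_distance_matrix(conf)
  all(d2[upper.tri(d2)] >= min_dist^2)
}

# ---- spin string <-> bitstring <-> basis index conversions -------------------

#' Convert spins to the basis-state index
#'
#' Qubit `q` (0-based) is spin position `q + 1`; bit 1 maps to spin `+1` and
#' qubit 0 is the least significant bit, so the index lies in
#' `[0, 2^length(spins))`.
#'
#' @param spins spin vector in `{-1, +1}`.
#' @return non-negative numeric scalar (exact for up to 52 qubits).
#' @export
spins_to_index <- function(spins) {
  if (length(spins) && !all(spins %in% c(-1, 1))) {
    stop("spin values must be -1 or +1", call. = FALSE)
  }
  if (!length(spins)) return(0)
  bits <- (spins + 1) / 2
  sum(bits * 2^(seq_along(bits) - 1L))
}

#' Convert a basis-state index to spins
#'
#' @param index basis-state index in `[0, 2^num_qubits)`.
#' @param num_qubits number of qubits (spin positions).
#' @return spin vector of length `num_qubits`.
#' @export
index_to_spins <- function(index, num_qubits) {
  stopifnot(index >= 0, index < 2^num_qubits)
  if (num_qubits == 0L) return(numeric(0))
  bits <- (index %/% 2^(seq_len(num_qubits) - 1L)) %% 2
  2 * bits - 1
}

#' @rdname spins_to_index
#' @export
spins_to_bitstring <- function(spins) {
  if (length(spins) && !all(spins %in% c(-1, 1))) {
    stop("spin values must be -1 or +1", call. = FALSE)
  }
  paste(as.integer((spins + 1) / 2), collapse = "")
}

#' @rdname index_to_spins
#' @param bitstring character string of 0/1, first character = qubit 0.
#' @export
bitstring_to_spins <- function(bitstring) {
  bits <- as.integer(strsplit(bitstring, "")[[1L]])
  if (length(bits) && !all(bits %in% c(0L, 1L))) {
    stop("bitstring must contain only 0 and 1", call. = FALSE)
  }
  2 * bits - 1
}

# Squared distances for a batch of basis-state indices, returned as a
# length(states) x (N(N-1)/2) matrix in flat upper-triangle (column-major)
# order over all pairs i < j. Works on integer lattice coordinates (units of
# 1/sqrt(3)) so coincidence tests are exact. Shared by the enumeration oracle
# and the training-time structure cache.
states_d2_ut <- function(states, N) {
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  m <- length(states)
  u <- array(0, dim = c(m, N, 3L))
  u[, 2L, ] <- 1
  if (N > 2L) {
    for (b in 3L:N) {
      q0 <- 3L * (b - 3L)  # qubit offset of bead b's x spin
      for (ax in 1L:3L) {
        bit <- (states %/% 2^(q0 + ax - 1L)) %% 2
        u[, b, ax] <- u[, b - 1L, ax] + (2 * bit - 1)
      }
    }
  }
  d2 <- matrix(0, m, nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1L]; j <- idx[p, 2L]
    d2[, p] <- ((u[, i, 1L] - u[, j, 1L])^2 +
                (u[, i, 2L] - u[, j, 2L])^2 +
                (u[, i, 3L] - u[, j, 3L])^2) / 3
  }
  d2
}

# ---- export ------------------------------------------------------------------

#' Write a conformation as xyz-style text
#'
#' One "x y z" row per bead; no header, no chemical semantics.
#'
#' @param conf a `conformation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conf, path) {
  utils::write.table(format(unclass(conf), digits = 12L), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' JSON record of a conformation
#'
#' @param conf a `conformation`.
#' @return a JSON string with fields `N`, `spins`, `coords`.
#' @export
conformation_json <- function(conf) {
  jsonlite::toJSON(list(N = nrow(conf),
                        spins = attr(conf, "spins"),
                        coords = unclass(conf)),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
as.data.frame.conformation <- function(x, ...) {
  data.frame(bead = seq_len(nrow(x)),
             x = x[, 1L], y = x[, 2L], z = x[, 3L])
}
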