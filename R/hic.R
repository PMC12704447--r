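#' Contact-frequency matrix
#'
#' Wraps a dense symmetric nonnegative Hi-C contact-frequency matrix.
#' Rows/columns whose frequencies are all zero (unmappable bins) are dropped,
#' with the retained bin indices kept as an attribute. The calibration unit
#' `f_unit` — the minimum nonzero frequency between adjacent loci — is
#' derived on construction.
#'
#' Matrix balancing is accepted as input (e.g. a balanced matrix from the
#' cooler ecosystem) but never performed here.
#'
#' @param f square numeric matrix, symmetric and nonnegative.
#' @return an object of class `frequency_matrix` with attributes `f_unit`
#'   and `kept_bins`.
#' @export
frequency_matrix <- function(f) {
  f <- as.matrix(f)
  dimnames(f) <- NULL
  if (nrow(f) != ncol(f)) stop("frequency matrix must be square", call. = FALSE)
  if (any(f < 0)) stop("frequencies must be nonnegative", call. = FALSE)
  if (!isTRUE(all.equal(f, t(f)))) {
    stop("frequency matrix must be symmetric", call. = FALSE)
  }
  keep <- which(rowSums(f) > 0 | colSums(f) > 0)
  if (!length(keep)) stop("frequency matrix is all zero", call. = FALSE)
  f <- f[keep, keep, drop = FALSE]
  n <- nrow(f)
  adj <- f[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  adj <- adj[adj > 0]
  if (!length(adj)) {
    stop("calibration error: all adjacent-locus frequencies are zero",
         call. = FALSE)
  }
  structure(f, class = "frequency_matrix", f_unit = min(adj),
            kept_bins = keep)
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("Contact-frequency matrix:", nrow(x), "bins, f_unit =",
      attr(x, "f_unit"), "\n")
  invisible(x)
}

#' Read a dense frequency matrix from whitespace/tab-delimited text
#'
#' @param path file path.
#' @return a [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path) {
  frequency_matrix(as.matrix(utils::read.table(path, header = FALSE)))
}

#' Calibration configuration
#'
#' The inverse-power exponent `lambda` of the distance-frequency relation
#' `D[i,j] ~ f[i,j]^(-lambda)`; values of 1/3, 1/2 and 2/3 are typical.
#'
#' @param lambda inverse-power exponent, `> 0` (default 1/3).
#' @param r contact radius (default 1.5).
#' @return an object of class `calibration_config`.
#' @export
calibration_config <- function(lambda = 1 / 3, r = 1.5) {
  stopifnot(lambda > 0, r > 0)
  structure(list(lambda = lambda, r = r), class = "calibration_config")
}

#' Binarize a frequency matrix into a contact map
#'
#' Entry `(i, j)` becomes a contact when `f[i,j] / f_unit >= r^(-1/lambda)`.
#' The diagonal and adjacent entries are computed like any other but are
#' never scored by the likelihood (sequence separation below 2).
#'
#' @param fm a [frequency_matrix()].
#' @param cal a [calibration_config()].
#' @return a [contact_map()].
#' @export
binarize_frequencies <- function(fm, cal = calibration_config()) {
  threshold <- cal$r^(-1 / cal$lambda)
  m <- 1 * (unclass(fm) / attr(fm, "f_unit") >= threshold)
  contact_map(m)
}

#' Inferred contact probability from model distances
#'
#' Probability 1 within the contact radius and inverse-power decay
#' `(r / D)^(1/lambda)` outside it. With `lambda = 1/3` this is the cube-law
#' special case. Non-increasing in `D` and continuous at `D = r`.
#'
#' @param d2 squared-distance matrix (e.g. [squared_distance_matrix()] of
#'   one structure, or an ensemble mean of such matrices).
#' @param cal a [calibration_config()].
#' @return matrix of contact probabilities in `[0, 1]`, unit diagonal.
#' @export
inferred_contact_matrix <- function(d2, cal = calibration_config()) {
  if (any(d2 < 0)) stop("distances must be nonnegative", call. = FALSE)
  D <- sqrt(d2)
  out <- ifelse(D <= cal$r, 1, (cal$r / pmax(D, .Machine$double.eps))^(1 / cal$lambda))
  out
}

#' Ensemble-mean inferred contact matrix
#'
#' Decodes every distinct sampled state, drops structures containing a
#' spatial clash (any pairwise distance below 1/4), and returns the
#' count-weighted mean of the per-structure inferred contact matrices.
#'
#' @param ens a [conformation_ensemble()].
#' @param cal a [calibration_config()].
#' @return list with `inferred` (mean probability matrix), `kept_shots`,
#'   and `dropped_shots` (shots on clash-containing structures).
#' @export
ensemble_mean_inferred <- function(ens, cal = calibration_config()) {
  N <- ens$N
  d2 <- states_d2_ut(ens$index, N)
  ok <- rowSums(d2 < 0.0625) == 0L
  if (!any(ok)) {
    stop("all sampled structures contain spatial clashes", call. = FALSE)
  }
  w <- ens$count[ok] / sum(ens$count[ok])
  inf_rows <- inferred_contact_matrix(d2[ok, , drop = FALSE], cal)
  mean_row <- as.numeric(crossprod(inf_rows, w))
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  m <- diag(N)
  m[idx] <- mean_row
  m[idx[, 2:1, drop = FALSE]] <- mean_row
  list(inferred = m, kept_shots = sum(ens$count[ok]),
       dropped_shots = sum(ens$count[!ok]))
}
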