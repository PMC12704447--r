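#' Binary contact map
#'
#' A symmetric 0/1 matrix with zero diagonal recording which bead pairs are
#' in contact. Entries at sequence separation below 2 may be stored but are
#' never scored by the likelihood (see [structure_log_likelihood()]).
#'
#' @param m square numeric matrix of 0/1 entries. An asymmetric input is
#'   symmetrised by logical OR of the two triangles, with a warning.
#' @return an object of class `contact_map` (a binary matrix).
#' @export
contact_map <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("contact map must be square", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("contact map entries must be 0 or 1",
                                 call. = FALSE)
  if (!isTRUE(all.equal(m, t(m)))) {
    warning("asymmetric contact map; symmetrising by logical OR")
    m <- 1 * ((m + t(m)) > 0)
  }
  diag(m) <- 0
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  structure(m, class = "contact_map")
}

#' Build a contact map from a list of contacting pairs
#'
#' @param pairs two-column matrix of bead indices (1-based, any order), or
#'   zero rows for the empty map.
#' @param N bead count.
#' @return a [contact_map()].
#' @export
contact_map_from_pairs <- function(pairs, N) {
  m <- matrix(0, N, N)
  pairs <- as.matrix(pairs)
  if (nrow(pairs)) {
    m[pairs] <- 1
    m[pairs[, 2:1, drop = FALSE]] <- 1
  }
  contact_map(m)
}

#' @export
print.contact_map <- function(x, ...) {
  n_contacts <- sum(unclass(x)[upper.tri(x)])
  cat("Contact map:", nrow(x), "beads,", n_contacts, "contacts\n")
  invisible(x)
}

#' Read / write a contact map as tab-delimited text
#'
#' Dense 0/1 matrix, no header. On read, an asymmetric matrix is symmetrised
#' by logical OR with a warning.
#'
#' @param path file path.
#' @return [read_contact_map()] returns a `contact_map`;
#'   [write_contact_map()] returns `path` invisibly.
#' @export
read_contact_map <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  contact_map(m)
}

#' @rdname read_contact_map
#' @param pc a [contact_map()].
#' @export
write_contact_map <- function(pc, path) {
  utils::write.table(unclass(pc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
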