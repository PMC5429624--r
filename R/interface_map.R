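# Interface map: residue-nucleotide contacts from 3D coordinates and the
# binding / non-binding labels they induce on both chains.

#' Detect residue-nucleotide contacts
#'
#' A residue i and nucleotide j are in contact when their minimum
#' heavy-atom-to-heavy-atom distance is at most `cutoff`. A residue
#' (nucleotide) is labelled binding iff it appears in at least one contact.
#' Hydrogens are never considered (the reader already drops them).
#'
#' @param complex An [rpi_complex()] with coordinates on both chains.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return An object of class `rpi_contact_map`: `contacts` (data frame with
#'   `residue`, `nucleotide`, `min_distance`), `cutoff`, `residue_labels` and
#'   `nucleotide_labels` (logical vectors), `n_residues`, `n_nucleotides`.
#' @export
find_contacts <- function(complex, cutoff = 5.0) {
  stopifnot(inherits(complex, "rpi_complex"))
  np <- length(complex$protein$index)
  nr <- length(complex$rna$index)
  contacts <- data.frame(residue = integer(0), nucleotide = integer(0),
                         min_distance = numeric(0))
  if (np == 0 || nr == 0) {
    warning("empty chain: no contacts computed")
  } else {
    pa <- do.call(rbind, complex$protein$atoms)
    pidx <- rep(seq_len(np), vapply(complex$protein$atoms, nrow, integer(1)))
    ra <- do.call(rbind, complex$rna$atoms)
    ridx <- rep(seq_len(nr), vapply(complex$rna$atoms, nrow, integer(1)))
    # squared cross-distances between all heavy atoms of the two chains
    d2 <- outer(rowSums(pa^2), rowSums(ra^2), `+`) - 2 * (pa %*% t(ra))
    d2[d2 < 0] <- 0
    # minimum per residue-nucleotide block
    dmin <- matrix(Inf, np, nr)
    for (b in seq_len(nrow(d2))) {
      i <- pidx[b]
      dmin[i, ] <- pmin(dmin[i, ],
                        vapply(split(d2[b, ], ridx), min, numeric(1)))
    }
    dmin <- sqrt(dmin)
    hit <- which(dmin <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      ord <- order(hit[, 1], hit[, 2])
      contacts <- data.frame(residue = hit[ord, 1], nucleotide = hit[ord, 2],
                             min_distance = dmin[hit][ord])
    }
  }
  structure(
    list(contacts = contacts, cutoff = cutoff,
         residue_labels = seq_len(np) %in% contacts$residue,
         nucleotide_labels = seq_len(nr) %in% contacts$nucleotide,
         n_residues = np, n_nucleotides = nr),
    class = "rpi_contact_map"
  )
}

#' Construct a contact map from explicit pairs
#'
#' Used by the synthetic generator and by tests; labels are derived from the
#' pair list exactly as in [find_contacts()].
#'
#' @param pairs Two-column matrix/data frame of (residue, nucleotide) indices.
#' @param n_residues,n_nucleotides Chain lengths.
#' @param cutoff Annotation only.
#' @return An `rpi_contact_map`.
#' @export
contact_map <- function(pairs, n_residues, n_nucleotides, cutoff = NA_real_) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs)) {
    storage.mode(pairs) <- "integer"
    stopifnot(all(pairs[, 1] >= 1), all(pairs[, 1] <= n_residues),
              all(pairs[, 2] >= 1), all(pairs[, 2] <= n_nucleotides))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  contacts <- data.frame(residue = as.integer(pairs[, 1][seq_len(nrow(pairs))]),
                         nucleotide = as.integer(pairs[, 2][seq_len(nrow(pairs))]),
                         min_distance = rep(NA_real_, nrow(pairs)))
  structure(
    list(contacts = contacts, cutoff = cutoff,
         residue_labels = seq_len(n_residues) %in% contacts$residue,
         nucleotide_labels = seq_len(n_nucleotides) %in% contacts$nucleotide,
         n_residues = n_residues, n_nucleotides = n_nucleotides),
    class = "rpi_contact_map"
  )
}

#' @export
print.rpi_contact_map <- function(x, ...) {
  s <- summarize_interface(x)
  cat("<rpi_contact_map> ", s[["n_contacts"]], " contacts (cutoff ",
      x$cutoff, " A)\n  residues: ", s[["n_binding_residues"]], " binding / ",
      s[["n_nonbinding_residues"]], " non-binding\n  nucleotides: ",
      s[["n_binding_nucleotides"]], " binding / ",
      s[["n_nonbinding_nucleotides"]], " non-binding\n", sep = "")
  invisible(x)
}

#' Summarise an interface map
#'
#' @param map An `rpi_contact_map`.
#' @return Named integer vector: binding / non-binding counts per side and the
#'   number of contacts.
#' @export
summarize_interface <- function(map) {
  stopifnot(inherits(map, "rpi_contact_map"))
  c(n_binding_residues = sum(map$residue_labels),
    n_nonbinding_residues = sum(!map$residue_labels),
    n_binding_nucleotides = sum(map$nucleotide_labels),
    n_nonbinding_nucleotides = sum(!map$nucleotide_labels),
    n_contacts = nrow(map$contacts))
}

#' Write a contact map as TSV
#'
#' @param map An `rpi_contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(map, path) {
  utils::write.table(map$contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
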