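# Labeled complex bundles: the unit the statistics and prediction layers work
# on — sequences, local-conformation strings, binding labels and contacts for
# one protein-RNA pair, with optional structure-derived per-residue features.

#' Assemble a labeled bundle from a 3D complex
#'
#' Computes backbone dihedrals and the PLC string, the RLC string from the
#' complex's dot-bracket (all-`l` with a warning when absent), contacts and
#' binding labels at `cutoff`, relative solvent accessibility (on the unbound
#' protein) and side-chain burial.
#'
#' @param complex An [rpi_complex()].
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param class_tag Functional class,
#'   one of `"enzymes"`, `"structural"`, `"regulatory"`, `"other"`.
#' @param conservation Optional per-residue conservation scores (defaults to 0,
#'   carrying no signal but keeping the vector shape).
#' @return An object of class `rpi_bundle`.
#' @export
as_bundle <- function(complex, cutoff = 5.0, class_tag = "other",
                      conservation = NULL) {
  stopifnot(inherits(complex, "rpi_complex"))
  cx <- if (all(is.na(complex$protein$phi))) compute_dihedrals(complex) else complex
  map <- find_contacts(cx, cutoff)
  rlc <- if (is.null(cx$dot_bracket)) {
    warning("no dot-bracket on '", cx$source_id, "': RLC set to all-'l'")
    paste(rep("l", length(cx$rna$index)), collapse = "")
  } else assign_rlc(cx$dot_bracket)
  structure(list(
    id = cx$source_id,
    class_tag = class_tag,
    protein = list(
      seq = paste(cx$protein$seq, collapse = ""),
      plc = assign_plc(cx),
      labels = map$residue_labels,
      rsa = relative_sasa(cx$protein),
      sidechain = sidechain_environment(cx$protein),
      conservation = conservation
    ),
    rna = list(
      seq = paste(cx$rna$seq, collapse = ""),
      rlc = rlc,
      labels = map$nucleotide_labels
    ),
    contacts = map
  ), class = "rpi_bundle")
}

#' @export
print.rpi_bundle <- function(x, ...) {
  cat("<rpi_bundle> ", x$id, " (", x$class_tag, ")\n",
      "  protein: ", nchar(x$protein$seq), " residues, ",
      sum(x$protein$labels), " binding\n",
      "  rna:     ", nchar(x$rna$seq), " nucleotides, ",
      sum(x$rna$labels), " binding\n",
      "  contacts: ", nrow(.bundle_contacts(x)), "\n", sep = "")
  invisible(x)
}

# contact pairs of a bundle as a plain 2-column integer matrix
.bundle_contacts <- function(bundle) {
  cm <- bundle$contacts
  if (inherits(cm, "rpi_contact_map"))
    cbind(cm$contacts$residue, cm$contacts$nucleotide)
  else matrix(as.integer(as.matrix(cm)), ncol = 2)
}

.bundle_map <- function(bundle) {
  if (inherits(bundle$contacts, "rpi_contact_map")) bundle$contacts
  else contact_map(.bundle_contacts(bundle),
                   nchar(bundle$protein$seq), nchar(bundle$rna$seq))
}
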