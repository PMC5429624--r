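# Reference tables: structural-alphabet prototypes, residue scales, atom radii.

.rpi_cache <- new.env(parent = emptyenv())

.read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rpibind")
  if (!nzchar(path)) stop("missing package data file: ", file)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Protein-block prototype dihedral table
#'
#' The 16 reference fragments of the protein-block structural alphabet. Each
#' block is described by the eight backbone dihedrals of a 5-residue fragment:
#' psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2).
#'
#' @return A 16 x 8 numeric matrix (degrees) with rownames `a`..`p`.
#' @export
plc_prototypes <- function() {
  if (is.null(.rpi_cache$pb)) {
    tab <- .read_extdata("pb_prototypes.tsv")
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$letter
    stopifnot(nrow(m) == 16L, ncol(m) == 8L)
    .rpi_cache$pb <- m
  }
  .rpi_cache$pb
}

# 8 scalar scales per amino acid (rownames = one-letter codes).
aa_scale_table <- function() {
  if (is.null(.rpi_cache$aa)) {
    tab <- .read_extdata("aa_scales.tsv")
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$aa
    .rpi_cache$aa <- m
  }
  .rpi_cache$aa
}

max_asa_table <- function() {
  if (is.null(.rpi_cache$asa)) {
    tab <- .read_extdata("max_asa.tsv")
    v <- tab$max_asa
    names(v) <- tab$aa
    .rpi_cache$asa <- v
  }
  .rpi_cache$asa
}

# Alphabets -------------------------------------------------------------------

#' Symbol alphabets used by the encoders
#'
#' @return Character vector of symbols: 20 amino acids, 4 nucleotides,
#'   16 protein-block letters (PLC, `a`..`p`), or the 12 RNA local-conformation
#'   letters (RLC, `a`..`l`).
#' @param which One of `"aa"`, `"nt"`, `"plc"`, `"rlc"`.
#' @export
rpi_alphabet <- function(which = c("aa", "nt", "plc", "rlc")) {
  switch(match.arg(which),
    aa  = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    nt  = c("A", "C", "G", "U"),
    plc = letters[1:16],
    rlc = letters[1:12]
  )
}

# RLC class semantics: a loop (hairpin), b stem, c stem branch,
# d/h left/right internal loop, e/i left/right bulge,
# f/j left/right internal-loop branch, g/k left/right bulge branch, l unknown.
rlc_class_names <- function() {
  c(a = "loop", b = "stem", c = "stem branch",
    d = "left internal loop", e = "bulge left",
    f = "left internal loop branch", g = "bulge left branch",
    h = "right internal loop", i = "bulge right",
    j = "right internal loop branch", k = "bulge right branch",
    l = "unknown")
}

# Residue name maps -----------------------------------------------------------

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common modified residues
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", PCA = "Q",
  HYP = "P", MLY = "K", M3L = "K", CME = "C", KCX = "K"
)

.nt_names <- c(
  A = "A", C = "C", G = "G", U = "U",
  # common modified nucleotides
  PSU = "U", `5MU` = "U", H2U = "U", `4SU` = "U", `1MA` = "A", `2MG` = "G",
  M2G = "G", `7MG` = "G", OMG = "G", OMC = "C", `5MC` = "C", UMS = "U",
  CCC = "C", `A2M` = "A"
)

.solvent_names <- c("HOH", "WAT", "DOD", "H2O")

aa_one_letter <- function(resname) {
  out <- unname(.aa3to1[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

nt_one_letter <- function(resname) {
  out <- unname(.nt_names[toupper(resname)])
  out[is.na(out)] <- "N"
  out
}

# van der Waals radii by element (A); default carbon-like for unknowns.
vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
  out <- r[toupper(element)]
  out[is.na(out)] <- 1.70
  unname(out)
}
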