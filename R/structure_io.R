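# Structure I/O: read protein-RNA complexes from PDB files, expose clean
# per-chain residue/nucleotide records, compute backbone dihedrals.

#' Construct a protein-RNA complex record
#'
#' Container for one protein chain and one RNA chain. Usually built by
#' [read_complex()]; exposed so synthetic complexes can be assembled in code.
#'
#' @param protein,rna Chain lists as produced by the reader: `chain_id`,
#'   `index` (1-based ordinals), `name` (3-letter/residue names), `seq`
#'   (one-letter codes, `X`/`N` for nonstandard), `auth` (author numbering,
#'   annotation only), `atoms` (list of n x 3 coordinate matrices, rownames =
#'   atom names, `"element"` attribute), and for proteins `phi`/`psi`
#'   (degrees, `NA` where undefined).
#' @param source_id Identifier such as `"3OUY:A-B"`.
#' @param dot_bracket Optional RNA secondary structure; must be balanced and
#'   the same length as the RNA chain.
#' @return An object of class `rpi_complex`.
#' @export
rpi_complex <- function(protein, rna, source_id = "complex", dot_bracket = NULL) {
  stopifnot(is.list(protein), is.list(rna))
  if (length(protein$index) && any(diff(protein$index) <= 0))
    stop("protein residue indices must be strictly increasing")
  if (length(rna$index) && any(diff(rna$index) <= 0))
    stop("nucleotide indices must be strictly increasing")
  if (!all(rna$seq %in% c("A", "C", "G", "U", "N")))
    stop("RNA bases must be in {A, C, G, U, N}")
  if (!is.null(dot_bracket)) {
    if (nchar(dot_bracket) != length(rna$index))
      stop("dot_bracket length must equal the number of nucleotides")
    parse_dot_bracket(dot_bracket)  # validates balance
  }
  structure(
    list(source_id = source_id, protein = protein, rna = rna,
         dot_bracket = dot_bracket),
    class = "rpi_complex"
  )
}

#' @export
print.rpi_complex <- function(x, ...) {
  cat("<rpi_complex> ", x$source_id, "\n",
      "  protein chain ", x$protein$chain_id, ": ",
      length(x$protein$index), " residues\n",
      "  rna chain     ", x$rna$chain_id, ": ",
      length(x$rna$index), " nucleotides\n", sep = "")
  if (!is.null(x$dot_bracket)) cat("  dot-bracket: ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

# Classify residues of a bio3d atom table into protein / rna / other.
.residue_kind <- function(resname, atom_names) {
  if (toupper(resname) %in% names(.aa3to1) || "CA" %in% atom_names &&
      ("N" %in% atom_names || "C" %in% atom_names)) return("protein")
  if (toupper(resname) %in% names(.nt_names) ||
      any(c("C1'", "O2'", "O4'", "N9") %in% atom_names)) return("rna")
  "other"
}

.extract_chain <- function(atom, chain_id, path) {
  sel <- atom$chain == chain_id & atom$type %in% c("ATOM", "HETATM")
  if (!any(sel)) stop("chain not found: '", chain_id, "' in ", path)
  at <- atom[sel, , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% .solvent_names), , drop = FALSE]
  ## heavy atoms only
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("^[0-9]", "", at$elety), 1, 1), at$elesy))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain_id, "' has no heavy atoms")
  ## resolve altlocs: keep the highest-occupancy conformer per atom
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    i[which.max(occ[i])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  ## group into residues in file order
  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  rid <- factor(rkey, levels = unique(rkey))
  groups <- split(seq_len(nrow(at)), rid)
  ## single-atom residues are ions; drop them
  groups <- groups[lengths(groups) > 1L]
  if (length(groups) == 0) stop("chain '", chain_id, "' has no polymer residues")
  list(at = at, groups = groups)
}

.chain_records <- function(ch, kind) {
  at <- ch$at
  n <- length(ch$groups)
  name <- character(n); auth <- character(n)
  atoms <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ch$groups[[k]]
    name[k] <- at$resid[i[1]]
    auth[k] <- trimws(paste0(at$resno[i[1]],
                             ifelse(is.na(at$insert[i[1]]), "", at$insert[i[1]])))
    m <- cbind(at$x[i], at$y[i], at$z[i])
    if (any(!is.finite(m))) stop("non-finite coordinates in residue ", auth[k])
    rownames(m) <- at$elety[i]
    attr(m, "element") <- toupper(ifelse(is.na(at$elesy[i]) | at$elesy[i] == "",
                                         substr(gsub("^[0-9]", "", at$elety[i]), 1, 1),
                                         at$elesy[i]))
    atoms[[k]] <- m
  }
  seq <- if (kind == "protein") aa_one_letter(name) else nt_one_letter(name)
  out <- list(chain_id = at$chain[1], index = seq_len(n), name = name,
              seq = seq, auth = auth, atoms = atoms)
  if (kind == "protein") {
    out$phi <- rep(NA_real_, n)
    out$psi <- rep(NA_real_, n)
  }
  out
}

#' Read a protein-RNA complex from a PDB file
#'
#' Parses one protein chain and one RNA chain (first model only). Waters, ions
#' and hydrogens are excluded; alternate locations are resolved to the
#' highest-occupancy conformer; modified residues/nucleotides are mapped to
#' their parent one-letter code where known, otherwise `X`/`N`. Insertion codes
#' are flattened into the 1-based ordinal (author numbering is kept as the
#' `auth` annotation). Backbone dihedrals are computed for the protein chain.
#'
#' @param path Path to a PDB file.
#' @param protein_chain,rna_chain Chain identifiers.
#' @return An [rpi_complex()] object.
#' @export
read_complex <- function(path, protein_chain, rna_chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  pch <- .extract_chain(pdb$atom, protein_chain, path)
  rch <- .extract_chain(pdb$atom, rna_chain, path)
  kind_of <- function(ch) {
    kinds <- vapply(ch$groups, function(i) {
      .residue_kind(ch$at$resid[i[1]], ch$at$elety[i])
    }, character(1))
    names(which.max(table(kinds)))
  }
  if (kind_of(pch) != "protein")
    stop("chain '", protein_chain, "' is not a protein chain")
  if (kind_of(rch) != "rna")
    stop("chain '", rna_chain, "' is not an RNA chain")
  cx <- rpi_complex(
    protein = .chain_records(pch, "protein"),
    rna = .chain_records(rch, "rna"),
    source_id = paste0(tools::file_path_sans_ext(basename(path)), ":",
                       protein_chain, "-", rna_chain)
  )
  compute_dihedrals(cx)
}

#' Write a complex to a minimal PDB file
#'
#' Emits plain `ATOM` records (all stored heavy atoms, sequential numbering)
#' so that a complex round-trips through [read_complex()].
#'
#' @param complex An [rpi_complex()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(complex, path) {
  stopifnot(inherits(complex, "rpi_complex"))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  emit <- function(chain, nt = FALSE) {
    for (k in seq_along(chain$index)) {
      m <- chain$atoms[[k]]
      el <- attr(m, "element")
      for (a in seq_len(nrow(m))) {
        serial <<- serial + 1L
        nm <- rownames(m)[a]
        nm4 <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
        writeLines(sprintf(
          "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm4, substr(chain$name[k], 1, 3), chain$chain_id,
          chain$index[k] %% 10000L, m[a, 1], m[a, 2], m[a, 3], 1, 0,
          if (is.null(el)) substr(nm, 1, 1) else el[a]), con)
      }
    }
    writeLines("TER", con)
  }
  emit(complex$protein)
  emit(complex$rna, nt = TRUE)
  writeLines("END", con)
  invisible(path)
}

# Geometry ---------------------------------------------------------------------

# Torsion angle (degrees) defined by four points (rows of a 4x3 matrix).
# NA for degenerate (collinear) geometry.
.torsion <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  x12 <- c(n1[2] * n2[3] - n1[3] * n2[2],
           n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(x12 * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.backbone_atom <- function(chain, k, name) {
  m <- chain$atoms[[k]]
  i <- match(name, rownames(m))
  if (is.na(i)) return(NULL)
  m[i, ]
}

#' Compute backbone phi/psi dihedrals for the protein chain
#'
#' Fills the `phi`/`psi` slots of the protein chain: `phi[i]` from
#' C(i-1)-N(i)-CA(i)-C(i), `psi[i]` from N(i)-CA(i)-C(i)-N(i+1). Angles are in
#' (-180, 180] degrees; `NA` where a flanking residue or backbone atom is
#' missing, at chain termini, across chain breaks (CA-CA distance above
#' `break_cutoff`), or for degenerate (collinear) geometry.
#'
#' @param x An [rpi_complex()] or a protein chain list.
#' @param break_cutoff CA-CA distance (Angstrom) above which consecutive
#'   residues are treated as a chain break. Default 4.5.
#' @return Object of the same type with `phi`/`psi` filled in.
#' @export
compute_dihedrals <- function(x, break_cutoff = 4.5) {
  if (inherits(x, "rpi_complex")) {
    x$protein <- compute_dihedrals(x$protein, break_cutoff)
    return(x)
  }
  chain <- x
  n <- length(chain$index)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  if (n >= 2 && !is.null(chain$atoms)) {
    ca <- lapply(seq_len(n), function(k) .backbone_atom(chain, k, "CA"))
    linked <- vapply(seq_len(n - 1), function(k) {
      !is.null(ca[[k]]) && !is.null(ca[[k + 1]]) &&
        sqrt(sum((ca[[k]] - ca[[k + 1]])^2)) <= break_cutoff
    }, logical(1))
    for (k in seq_len(n)) {
      N  <- .backbone_atom(chain, k, "N")
      CA <- .backbone_atom(chain, k, "CA")
      C  <- .backbone_atom(chain, k, "C")
      if (k > 1 && linked[k - 1]) {
        Cm <- .backbone_atom(chain, k - 1, "C")
        if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(C))
          phi[k] <- .torsion(rbind(Cm, N, CA, C))
      }
      if (k < n && linked[k]) {
        Np <- .backbone_atom(chain, k + 1, "N")
        if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Np))
          psi[k] <- .torsion(rbind(N, CA, C, Np))
      }
    }
  }
  chain$phi <- phi
  chain$psi <- psi
  chain
}
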