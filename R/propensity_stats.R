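# Interface propensity statistics: symbol compositions at / outside the
# interface, log-odds preferences, and mutual interaction propensity (MIP)
# matrices, optionally stratified by functional class.

.as_symbols <- function(encoding) {
  if (length(encoding) == 1L && is.character(encoding) && nchar(encoding) != 1L)
    strsplit(encoding, "")[[1]]
  else as.character(encoding)
}

.known_strata <- c("enzymes", "structural", "regulatory", "other", "pooled")

#' Interface / non-interface symbol composition
#'
#' Counts each symbol over the binding and non-binding positions of an encoded
#' chain (or pooled chains) and normalises each column to frequencies.
#'
#' @param labels Logical (or 0/1) vector of binding labels.
#' @param encoding Symbol string or character vector of the same length
#'   (amino acids, bases, PLC or RLC letters).
#' @param alphabet Symbol set; defaults to the sorted unique symbols observed.
#' @param stratum Stratum tag, one of `r toString(.known_strata)`.
#' @return Object of class `rpi_composition`: data frame `table` with columns
#'   `symbol`, `count_interface`, `count_outside`, `freq_interface`,
#'   `freq_outside`, plus `stratum` and the totals.
#' @export
composition <- function(labels, encoding, alphabet = NULL, stratum = "pooled") {
  sym <- .as_symbols(encoding)
  labels <- as.logical(labels)
  stopifnot(length(sym) == length(labels))
  if (!stratum %in% .known_strata)
    stop("unknown stratum tag: ", stratum)
  if (is.null(alphabet)) alphabet <- sort(unique(sym))
  ci <- table(factor(sym[labels], levels = alphabet))
  co <- table(factor(sym[!labels], levels = alphabet))
  ni <- sum(ci); no <- sum(co)
  if (ni == 0) warning("no binding positions: interface column is all-zero")
  if (no == 0) warning("no non-binding positions: outside column is all-zero")
  structure(
    list(table = data.frame(
           symbol = alphabet,
           count_interface = as.integer(ci),
           count_outside = as.integer(co),
           freq_interface = if (ni > 0) as.numeric(ci) / ni else rep(0, length(ci)),
           freq_outside = if (no > 0) as.numeric(co) / no else rep(0, length(co)),
           stringsAsFactors = FALSE),
         stratum = stratum, n_interface = ni, n_outside = no),
    class = "rpi_composition"
  )
}

#' Log-odds preference of symbols at the interface
#'
#' Per symbol s: `ln((c_int(s)+a) / (N_int+aK)) - ln((c_out(s)+a) / (N_out+aK))`
#' with pseudocount `a` and alphabet size K, computed from raw counts. Natural
#' log throughout.
#'
#' @param table An `rpi_composition`.
#' @param pseudocount Pseudocount a (default 1), guarantees finite values.
#' @return Object of class `rpi_log_odds`: named numeric vector `values`,
#'   `pseudocount`, `stratum`.
#' @export
log_odds_preference <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "rpi_composition"), pseudocount >= 0)
  tb <- table$table
  K <- nrow(tb)
  a <- pseudocount
  v <- log((tb$count_interface + a) / (table$n_interface + a * K)) -
       log((tb$count_outside + a) / (table$n_outside + a * K))
  names(v) <- tb$symbol
  structure(list(values = v, pseudocount = a, stratum = table$stratum),
            class = "rpi_log_odds")
}

#' Mutual interaction propensity (MIP) matrix
#'
#' From a list of contacting symbol pairs (protein-side symbol, RNA-side
#' symbol) the raw count matrix n(i, j) is tabulated and each cell converted to
#' a log-odds propensity against the row-by-column independence expectation:
#' `ln((n_ij + a) * (N + a*R*C) / ((n_i. + a*C) * (n_.j + a*R)))` with alphabet
#' sizes R (rows) and C (columns). At `a = 0` a table of exact products has
#' propensity 0 everywhere.
#'
#' @param contacts Two-column character matrix/data frame of symbol pairs.
#' @param protein_alphabet,rna_alphabet Row/column symbol sets.
#' @param pseudocount Pseudocount a (default 1).
#' @return Object of class `rpi_mip`: integer `counts` and numeric `propensity`
#'   matrices (rows = protein symbols, columns = RNA symbols), `pseudocount`.
#' @export
mip <- function(contacts, protein_alphabet, rna_alphabet, pseudocount = 1) {
  contacts <- as.matrix(contacts)
  if (nrow(contacts) == 0) stop("empty contact list: nothing to estimate")
  if (!all(contacts[, 1] %in% protein_alphabet))
    stop("protein-side symbol outside declared alphabet")
  if (!all(contacts[, 2] %in% rna_alphabet))
    stop("RNA-side symbol outside declared alphabet")
  counts <- table(factor(contacts[, 1], levels = protein_alphabet),
                  factor(contacts[, 2], levels = rna_alphabet))
  counts <- matrix(as.integer(counts), nrow = length(protein_alphabet),
                   dimnames = list(protein_alphabet, rna_alphabet))
  mip_from_counts(counts, pseudocount)
}

#' @rdname mip
#' @param counts Pre-tabulated count matrix.
#' @export
mip_from_counts <- function(counts, pseudocount = 1) {
  a <- pseudocount
  R <- nrow(counts); C <- ncol(counts)
  N <- sum(counts)
  ri <- rowSums(counts); cj <- colSums(counts)
  prop <- log((counts + a) * (N + a * R * C)) -
    log(outer(ri + a * C, cj + a * R))
  structure(list(counts = counts, propensity = prop, pseudocount = a),
            class = "rpi_mip")
}

#' @export
print.rpi_mip <- function(x, ...) {
  cat("<rpi_mip> ", nrow(x$counts), "x", ncol(x$counts), " symbols, ",
      sum(x$counts), " contacts, pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Per-stratum propensity tables for all alphabets
#'
#' For each functional class (and pooled) computes composition and log-odds
#' tables over amino acids, nucleotides, PLCs and RLCs, plus the PLC x RLC and
#' amino-acid x nucleotide MIP matrices from the contact lists.
#'
#' @param bundles List of labeled complex bundles ([generate_labeled_complex()]
#'   or [as_bundle()]); each must carry a `class_tag` in
#'   `{enzymes, structural, regulatory, other}`.
#' @param pseudocount Pseudocount for log-odds and MIP.
#' @return Named list (one entry per observed stratum plus `"pooled"`), each
#'   with `composition`, `log_odds` (lists over alphabets `aa`, `nt`, `plc`,
#'   `rlc`) and `mip` (`plc_rlc`, `aa_nt`).
#' @export
stratify <- function(bundles, pseudocount = 1) {
  tags <- vapply(bundles, function(b) b$class_tag %||% "other", character(1))
  bad <- setdiff(unique(tags), setdiff(.known_strata, "pooled"))
  if (length(bad)) stop("unknown class tag(s): ", paste(bad, collapse = ", "))
  strata <- c(split(bundles, tags), list(pooled = bundles))
  lapply(strata, function(bs) {
    pull <- function(side, field) unlist(lapply(bs, function(b) {
      s <- b[[side]][[field]]
      if (is.character(s) && length(s) == 1L) strsplit(s, "")[[1]] else s
    }))
    plab <- pull("protein", "labels"); rlab <- pull("rna", "labels")
    comp <- list(
      aa  = composition(plab, pull("protein", "seq"), rpi_alphabet("aa")),
      nt  = composition(rlab, pull("rna", "seq"), rpi_alphabet("nt")),
      plc = composition(plab, pull("protein", "plc"),
                        c(rpi_alphabet("plc"), "Z")),
      rlc = composition(rlab, pull("rna", "rlc"), rpi_alphabet("rlc"))
    )
    pairs <- contact_symbol_pairs(bs)
    list(
      composition = comp,
      log_odds = lapply(comp, log_odds_preference, pseudocount = pseudocount),
      mip = list(
        plc_rlc = mip(pairs$plc_rlc, c(rpi_alphabet("plc"), "Z"),
                      rpi_alphabet("rlc"), pseudocount),
        aa_nt = mip(pairs$aa_nt, c(rpi_alphabet("aa"), "X"),
                    c(rpi_alphabet("nt"), "N"), pseudocount)
      )
    )
  })
}

# Collect (protein symbol, RNA symbol) pairs over all contacts of a bundle list.
contact_symbol_pairs <- function(bundles) {
  plc_rlc <- aa_nt <- matrix(character(0), ncol = 2)
  for (b in bundles) {
    cm <- b$contacts
    pr <- if (inherits(cm, "rpi_contact_map")) as.matrix(cm$contacts[, 1:2]) else as.matrix(cm)
    if (!nrow(pr)) next
    pseq <- .as_symbols(b$protein$seq); plc <- .as_symbols(b$protein$plc)
    rseq <- .as_symbols(b$rna$seq); rlc <- .as_symbols(b$rna$rlc)
    plc_rlc <- rbind(plc_rlc, cbind(plc[pr[, 1]], rlc[pr[, 2]]))
    aa_nt <- rbind(aa_nt, cbind(pseq[pr[, 1]], rseq[pr[, 2]]))
  }
  list(plc_rlc = plc_rlc, aa_nt = aa_nt)
}

#' Write propensity tables as tidy TSV
#'
#' @param strata Output of [stratify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_propensities <- function(strata, path) {
  rows <- do.call(rbind, lapply(names(strata), function(st) {
    do.call(rbind, lapply(names(strata[[st]]$composition), function(al) {
      tb <- strata[[st]]$composition[[al]]$table
      data.frame(alphabet = al, stratum = st, symbol = tb$symbol,
                 freq_interface = tb$freq_interface,
                 freq_outside = tb$freq_outside,
                 log_odds = unname(strata[[st]]$log_odds[[al]]$values))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
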