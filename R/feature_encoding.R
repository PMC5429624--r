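# Windowed feature encoding: fixed-length vectors per residue (step 1), per
# nucleotide (step 2), and per residue-nucleotide pair (step 3).

#' Feature configuration
#'
#' @param window Sliding-window size, odd, one of 3/5/7/9 (default 5, the size
#'   that performed best across steps).
#' @param pseudocount Pseudocount used when fitting descriptor tables.
#' @param protein_families Protein feature families to include, a subset of
#'   `mip` (interaction-propensity profile of the residue's amino acid against
#'   the 4 bases), `physchem` (7 scalar scales), `hydro` (hydrophobic index),
#'   `rsa`, `conservation`, `sidechain`, `plc_triplet` (structure descriptor).
#' @param rna_families RNA families, subset of `mono`, `di`, `tri`
#'   (nucleotide composition within the window) and `rlc_triplet`.
#' @param with_structure Convenience switch: `FALSE` drops the `plc_triplet` /
#'   `rlc_triplet` structure descriptors from both sides.
#' @return An object of class `rpi_feature_config`.
#' @export
rpi_feature_config <- function(window = 5, pseudocount = 1,
                               protein_families = c("mip", "physchem", "hydro",
                                                    "rsa", "conservation",
                                                    "sidechain", "plc_triplet"),
                               rna_families = c("mono", "di", "tri",
                                                "rlc_triplet"),
                               with_structure = TRUE) {
  if (!window %in% c(3, 5, 7, 9)) stop("window must be one of 3, 5, 7, 9")
  protein_families <- match.arg(protein_families,
    c("mip", "physchem", "hydro", "rsa", "conservation", "sidechain",
      "plc_triplet"), several.ok = TRUE)
  rna_families <- match.arg(rna_families,
    c("mono", "di", "tri", "rlc_triplet"), several.ok = TRUE)
  if (!with_structure) {
    protein_families <- setdiff(protein_families, "plc_triplet")
    rna_families <- setdiff(rna_families, "rlc_triplet")
  }
  structure(list(window = as.integer(window), pseudocount = pseudocount,
                 protein_families = protein_families,
                 rna_families = rna_families),
            class = "rpi_feature_config")
}

# Triplet log-odds descriptor ---------------------------------------------------

#' Fit a triplet log-odds descriptor table
#'
#' For every 3-letter word t of the given alphabet, the log-odds of occurring
#' centred at a binding vs a non-binding position:
#' `ln((c_pos(t)+a)/(N_pos+a*K^3)) - ln((c_neg(t)+a)/(N_neg+a*K^3))`,
#' counted over the overlapping triplets centred at each labelled position
#' (chain-terminal positions have no full triplet and are skipped).
#'
#' @param strings Encoding string or list of strings (PLC or RLC).
#' @param labels Logical label vector or list of vectors, matching `strings`.
#' @param alphabet Symbol set of the encoding (include `Z` for PLC strings).
#' @param pseudocount Pseudocount a > 0 (default 1).
#' @return Object of class `rpi_triplet_table`.
#' @export
fit_triplet_log_odds <- function(strings, labels, alphabet, pseudocount = 1) {
  if (!is.list(strings)) strings <- list(strings)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(strings) == length(labels), pseudocount > 0)
  cpos <- new.env(parent = emptyenv()); cneg <- new.env(parent = emptyenv())
  npos <- 0L; nneg <- 0L
  for (s in seq_along(strings)) {
    sym <- .as_symbols(strings[[s]])
    lab <- as.logical(labels[[s]])
    stopifnot(length(sym) == length(lab))
    n <- length(sym)
    if (n < 3) next
    for (i in 2:(n - 1)) {
      t <- paste0(sym[i - 1], sym[i], sym[i + 1])
      if (isTRUE(lab[i])) {
        cpos[[t]] <- (cpos[[t]] %||% 0L) + 1L; npos <- npos + 1L
      } else if (isFALSE(lab[i])) {
        cneg[[t]] <- (cneg[[t]] %||% 0L) + 1L; nneg <- nneg + 1L
      }
    }
  }
  if (npos + nneg == 0L) stop("empty training set: no labelled triplets")
  K3 <- length(alphabet)^3
  a <- pseudocount
  trips <- union(ls(cpos), ls(cneg))
  val <- vapply(trips, function(t) {
    log(((cpos[[t]] %||% 0L) + a) / (npos + a * K3)) -
      log(((cneg[[t]] %||% 0L) + a) / (nneg + a * K3))
  }, numeric(1))
  structure(list(values = val, alphabet = alphabet, pseudocount = a,
                 n_pos = npos, n_neg = nneg,
                 default = log(a / (npos + a * K3)) - log(a / (nneg + a * K3))),
            class = "rpi_triplet_table")
}

#' Look up triplet log-odds values
#'
#' @param table An `rpi_triplet_table`.
#' @param triplets Character vector of 3-letter words; unseen words get the
#'   pseudocount-only value, words containing symbols outside the alphabet 0.
#' @return Numeric vector.
#' @export
triplet_value <- function(table, triplets) {
  stopifnot(inherits(table, "rpi_triplet_table"))
  v <- table$values[triplets]
  v[is.na(v)] <- table$default
  bad <- !vapply(strsplit(triplets, ""),
                 function(s) all(s %in% table$alphabet), logical(1))
  v[bad] <- 0
  unname(v)
}

# Descriptor tables ------------------------------------------------------------

#' Fit all descriptor tables on a training set
#'
#' Fits, on the given (training) bundles only: the amino-acid x nucleotide MIP
#' matrix from the contact lists, and the PLC / RLC triplet log-odds tables
#' from the binding labels. These are the tables consumed by the encoders;
#' refit them inside each cross-validation training fold to avoid leakage.
#'
#' @param bundles List of labeled bundles.
#' @param config An [rpi_feature_config()].
#' @return Object of class `rpi_tables` with `mip_aa`, `triplet_plc`,
#'   `triplet_rlc`.
#' @export
fit_feature_tables <- function(bundles, config = rpi_feature_config()) {
  a <- config$pseudocount
  pairs <- contact_symbol_pairs(bundles)$aa_nt
  structure(list(
    mip_aa = if (nrow(pairs)) {
      mip(pairs, c(rpi_alphabet("aa"), "X"), c(rpi_alphabet("nt"), "N"),
          max(a, 1))
    } else NULL,
    triplet_plc = fit_triplet_log_odds(
      lapply(bundles, function(b) b$protein$plc),
      lapply(bundles, function(b) b$protein$labels),
      c(rpi_alphabet("plc"), "Z"), max(a, 1e-9)),
    triplet_rlc = fit_triplet_log_odds(
      lapply(bundles, function(b) b$rna$rlc),
      lapply(bundles, function(b) b$rna$labels),
      rpi_alphabet("rlc"), max(a, 1e-9))
  ), class = "rpi_tables")
}

# Window machinery --------------------------------------------------------------

# Per-residue scalar feature matrix (columns named by family:scale).
.protein_scalars <- function(bundle, config, tables) {
  seq <- .as_symbols(bundle$protein$seq)
  n <- length(seq)
  fam <- config$protein_families
  cols <- list()
  sc <- aa_scale_table()
  lookup <- function(scales) {
    m <- sc[, scales, drop = FALSE]
    out <- m[match(seq, rownames(m)), , drop = FALSE]
    for (j in seq_len(ncol(out)))  # nonstandard residue -> scale mean
      out[is.na(out[, j]), j] <- mean(m[, j])
    out
  }
  if ("mip" %in% fam) {
    if (is.null(tables$mip_aa)) stop("mip family requires a fitted MIP table")
    prop <- tables$mip_aa$propensity[, rpi_alphabet("nt"), drop = FALSE]
    m <- prop[match(seq, rownames(prop)), , drop = FALSE]
    m[is.na(m)] <- 0
    colnames(m) <- paste0("mip:", rpi_alphabet("nt"))
    cols$mip <- m
  }
  if ("physchem" %in% fam) {
    m <- lookup(c("kd", "polarity", "charge", "volume", "pi", "helix", "sheet"))
    colnames(m) <- paste0("physchem:", colnames(m))
    cols$physchem <- m
  }
  if ("hydro" %in% fam) {
    m <- lookup("fp")
    colnames(m) <- "hydro:fp"
    cols$hydro <- m
  }
  neutral <- function(x, default) {
    v <- if (is.null(x)) rep(default, n) else as.numeric(x)
    stopifnot(length(v) == n)
    matrix(v, ncol = 1)
  }
  if ("rsa" %in% fam) {
    m <- neutral(bundle$protein$rsa, 0.5); colnames(m) <- "rsa:rel"
    cols$rsa <- m
  }
  if ("conservation" %in% fam) {
    m <- neutral(bundle$protein$conservation, 0); colnames(m) <- "conservation:score"
    cols$conservation <- m
  }
  if ("sidechain" %in% fam) {
    m <- neutral(bundle$protein$sidechain, 0.5); colnames(m) <- "sidechain:burial"
    cols$sidechain <- m
  }
  cols
}

# Expand an n x q per-position matrix into windowed features; off-chain
# positions are padded with the chain mean of each column.
.window_expand <- function(V, window) {
  n <- nrow(V)
  h <- (window - 1L) %/% 2L
  pad <- colMeans(V)
  blocks <- lapply(-h:h, function(off) {
    idx <- seq_len(n) + off
    ok <- idx >= 1 & idx <= n
    out <- matrix(pad, n, ncol(V), byrow = TRUE)
    out[ok, ] <- V[idx[ok], , drop = FALSE]
    colnames(out) <- paste0(colnames(V), "_w", off)
    out
  })
  do.call(cbind, blocks)
}

# Triplet log-odds of the (window - 2) overlapping triplets inside each window;
# triplets that would extend past the chain contribute a neutral 0.
.window_triplets <- function(sym, window, table, prefix) {
  n <- length(sym)
  h <- (window - 1L) %/% 2L
  offs <- (-h + 1L):(h - 1L)
  out <- matrix(0, n, length(offs))
  colnames(out) <- paste0(prefix, ":triplet_w", offs)
  for (c in seq_along(offs)) {
    ctr <- seq_len(n) + offs[c]
    ok <- ctr >= 2 & ctr <= n - 1
    if (any(ok)) {
      trips <- paste0(sym[ctr[ok] - 1], sym[ctr[ok]], sym[ctr[ok] + 1])
      out[ok, c] <- triplet_value(table, trips)
    }
  }
  out
}

.make_samples <- function(features, labels, center, complex, side, groups) {
  structure(list(features = features, labels = labels, center = center,
                 complex = complex, side = side, groups = groups),
            class = "rpi_samples")
}

#' @export
print.rpi_samples <- function(x, ...) {
  cat("<rpi_samples> side=", x$side, ": ", nrow(x$features), " samples x ",
      ncol(x$features), " features (", sum(x$labels %in% TRUE), " positive)\n",
      "  families: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Encode protein residues as windowed feature vectors
#'
#' One sample per residue: per-residue scalar features (interaction-propensity
#' profile, physicochemical scales, hydrophobic index, relative accessibility,
#' conservation, side-chain burial) concatenated across the window positions
#' (chain-mean padding at termini), followed by the triplet log-odds of the
#' overlapping PLC triplets inside the window. The label is the centre
#' residue's binding label.
#'
#' @param bundle A labeled bundle (see [as_bundle()] /
#'   [generate_labeled_complex()]).
#' @param config An [rpi_feature_config()].
#' @param tables An `rpi_tables` from [fit_feature_tables()].
#' @return An `rpi_samples` object (features matrix, labels, feature-group
#'   slices, provenance).
#' @export
encode_protein_windows <- function(bundle, config = rpi_feature_config(),
                                   tables) {
  seq <- .as_symbols(bundle$protein$seq)
  n <- length(seq)
  if (n == 0)
    return(.make_samples(matrix(numeric(0), 0, 0), logical(0), integer(0),
                         character(0), "protein", list()))
  scalars <- .protein_scalars(bundle, config, tables)
  blocks <- list(); groups <- list(); p <- 0L
  add <- function(name, m) {
    blocks[[name]] <<- m
    groups[[name]] <<- p + seq_len(ncol(m))
    p <<- p + ncol(m)
  }
  for (nm in names(scalars)) add(nm, .window_expand(scalars[[nm]], config$window))
  if ("plc_triplet" %in% config$protein_families) {
    plc <- .as_symbols(bundle$protein$plc)
    stopifnot(length(plc) == n)
    add("plc_triplet",
        .window_triplets(plc, config$window, tables$triplet_plc, "plc"))
  }
  feats <- do.call(cbind, blocks)
  labels <- if (is.null(bundle$protein$labels)) rep(NA, n)
            else as.logical(bundle$protein$labels)
  .make_samples(feats, labels, seq_len(n),
                rep(bundle$id %||% "complex", n), "protein", groups)
}

#' Encode RNA nucleotides as windowed feature vectors
#'
#' One sample per nucleotide: mono- (4), di- (16) and tri-nucleotide (64)
#' composition within the window (frequencies over the in-chain window
#' positions), followed by the RLC triplet log-odds of the overlapping
#' triplets. The label is the centre nucleotide's binding label.
#'
#' @inheritParams encode_protein_windows
#' @return An `rpi_samples` object.
#' @export
encode_rna_windows <- function(bundle, config = rpi_feature_config(), tables) {
  seq <- .as_symbols(bundle$rna$seq)
  n <- length(seq)
  if (n == 0)
    return(.make_samples(matrix(numeric(0), 0, 0), logical(0), integer(0),
                         character(0), "rna", list()))
  h <- (config$window - 1L) %/% 2L
  nt <- rpi_alphabet("nt")
  kmers <- function(k) {
    apply(expand.grid(rep(list(nt), k))[, k:1, drop = FALSE], 1, paste,
          collapse = "")
  }
  blocks <- list(); groups <- list(); p <- 0L
  add <- function(name, m) {
    blocks[[name]] <<- m
    groups[[name]] <<- p + seq_len(ncol(m))
    p <<- p + ncol(m)
  }
  comp_block <- function(k, name) {
    words <- kmers(k)
    m <- matrix(0, n, length(words))
    colnames(m) <- paste0(name, ":", words)
    for (i in seq_len(n)) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      if (hi - lo + 1L >= k) {
        starts <- lo:(hi - k + 1L)
        obs <- vapply(starts, function(s) paste(seq[s:(s + k - 1L)],
                                                collapse = ""), character(1))
        tab <- table(factor(obs[obs %in% words], levels = words))
        if (sum(tab) > 0) m[i, ] <- as.numeric(tab) / sum(tab)
      }
    }
    m
  }
  if ("mono" %in% config$rna_families) add("mono", comp_block(1, "mono"))
  if ("di" %in% config$rna_families) add("di", comp_block(2, "di"))
  if ("tri" %in% config$rna_families) add("tri", comp_block(3, "tri"))
  if ("rlc_triplet" %in% config$rna_families) {
    rlc <- .as_symbols(bundle$rna$rlc)
    stopifnot(length(rlc) == n)
    add("rlc_triplet",
        .window_triplets(rlc, config$window, tables$triplet_rlc, "rlc"))
  }
  feats <- do.call(cbind, blocks)
  labels <- if (is.null(bundle$rna$labels)) rep(NA, n)
            else as.logical(bundle$rna$labels)
  .make_samples(feats, labels, seq_len(n),
                rep(bundle$id %||% "complex", n), "rna", groups)
}

#' Encode residue-nucleotide pairs
#'
#' Concatenates the protein window vector of residue i with the RNA window
#' vector of nucleotide j (protein first); the label is contact iff (i, j) is
#' in the contact map.
#'
#' @param protein_samples,rna_samples `rpi_samples` for the two sides of one
#'   complex, encoded under the same configuration.
#' @param pairs Two-column matrix of (residue, nucleotide) index pairs.
#' @param map Optional `rpi_contact_map` supplying labels; `NA` labels if
#'   missing.
#' @return An `rpi_samples` with `side = "pair"`; `center` is the pair matrix.
#' @export
encode_pair <- function(protein_samples, rna_samples, pairs, map = NULL) {
  stopifnot(inherits(protein_samples, "rpi_samples"),
            inherits(rna_samples, "rpi_samples"),
            protein_samples$side == "protein", rna_samples$side == "rna")
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  if (!identical(unique(protein_samples$complex),
                 unique(rna_samples$complex)))
    stop("protein and RNA samples come from different complexes")
  pf <- protein_samples$features[pairs[, 1], , drop = FALSE]
  rf <- rna_samples$features[pairs[, 2], , drop = FALSE]
  colnames(pf) <- paste0("p.", colnames(pf))
  colnames(rf) <- paste0("r.", colnames(rf))
  groups <- c(
    stats::setNames(protein_samples$groups,
                    paste0("p.", names(protein_samples$groups))),
    lapply(rna_samples$groups, function(ix) ix + ncol(pf))
  )
  names(groups)[-seq_along(protein_samples$groups)] <-
    paste0("r.", names(rna_samples$groups))
  labels <- if (is.null(map)) rep(NA, nrow(pairs)) else {
    key <- paste(map$contacts$residue, map$contacts$nucleotide)
    paste(pairs[, 1], pairs[, 2]) %in% key
  }
  .make_samples(cbind(pf, rf), labels, pairs,
                rep(unique(protein_samples$complex), nrow(pairs)), "pair",
                groups)
}

#' Combine sample sets from several complexes
#'
#' @param sample_list List of `rpi_samples` sharing one feature layout.
#' @return A single `rpi_samples`.
#' @export
bind_samples <- function(sample_list) {
  sample_list <- Filter(function(s) nrow(s$features) > 0, sample_list)
  stopifnot(length(sample_list) > 0)
  layouts <- lapply(sample_list, function(s) colnames(s$features))
  if (!all(vapply(layouts, identical, logical(1), layouts[[1]])))
    stop("feature layouts differ between sample sets")
  .make_samples(
    do.call(rbind, lapply(sample_list, `[[`, "features")),
    unlist(lapply(sample_list, `[[`, "labels")),
    do.call(if (sample_list[[1]]$side == "pair") rbind else c,
            lapply(sample_list, `[[`, "center")),
    unlist(lapply(sample_list, `[[`, "complex")),
    sample_list[[1]]$side,
    sample_list[[1]]$groups
  )
}
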