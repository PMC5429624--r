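# Step 3: the residue-nucleotide contact model, in its flat variant (all
# contacts as positives) and the cascade variant in which the step-1/step-2
# predictions gate the positive set and, at inference, the candidate pairs.

# neighbour-pair negative pool: for each contact (i, j), residue i paired with
# non-binding nucleotides within `radius` of j, and nucleotide j with
# non-binding residues within `radius` of i
.negative_pool <- function(contacts, map, radius) {
  if (!nrow(contacts)) return(matrix(integer(0), ncol = 2))
  out <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(contacts))) {
    i <- contacts[r, 1]; j <- contacts[r, 2]
    js <- setdiff(max(1, j - radius):min(map$n_nucleotides, j + radius), j)
    js <- js[!map$nucleotide_labels[js]]
    is <- setdiff(max(1, i - radius):min(map$n_residues, i + radius), i)
    is <- is[!map$residue_labels[is]]
    if (length(js)) out <- rbind(out, cbind(rep(i, length(js)), js))
    if (length(is)) out <- rbind(out, cbind(is, rep(j, length(is))))
  }
  unique(out)
}

#' Build the step-3 residue-nucleotide pair dataset
#'
#' Positives are the observed contacts; in cascade mode they are restricted to
#' contacts whose residue scored at least `thresholds[1]` at step 1 *and*
#' whose nucleotide scored at least `thresholds[2]` at step 2. Negatives are
#' near-miss pairs: each contact's residue paired with non-binding nucleotides
#' within the window radius of its partner (and vice versa), pooled and
#' subsampled to `negative_ratio` times the positives.
#'
#' @param bundles List of labeled bundles.
#' @param config An [rpi_feature_config()].
#' @param tables An `rpi_tables` fitted on the training complexes.
#' @param mode `"flat"` or `"cascade"`.
#' @param step1_scores,step2_scores Named lists (by bundle id) of per-position
#'   scores; required in cascade mode.
#' @param thresholds Step-1/step-2 decision thresholds, default `c(0.5, 0.5)`.
#' @param negative_ratio Negatives per positive (default 1).
#' @param seed Seed for the negative subsampling.
#' @return An `rpi_samples` with `side = "pair"`.
#' @export
build_step3_dataset <- function(bundles, config = rpi_feature_config(), tables,
                                mode = c("flat", "cascade"),
                                step1_scores = NULL, step2_scores = NULL,
                                thresholds = c(0.5, 0.5), negative_ratio = 1,
                                seed = 1) {
  mode <- match.arg(mode)
  if (mode == "cascade" && (is.null(step1_scores) || is.null(step2_scores)))
    stop("cascade mode requires step-1 and step-2 scores")
  radius <- (config$window - 1L) %/% 2L
  per_bundle <- list()
  n_pos_total <- 0L
  for (b in bundles) {
    map <- .bundle_map(b)
    pos <- .bundle_contacts(b)
    if (mode == "cascade" && nrow(pos)) {
      s1 <- step1_scores[[b$id]]; s2 <- step2_scores[[b$id]]
      keep <- s1[pos[, 1]] >= thresholds[1] & s2[pos[, 2]] >= thresholds[2]
      pos <- pos[keep, , drop = FALSE]
    }
    neg <- .negative_pool(.bundle_contacts(b), map, radius)
    per_bundle[[b$id]] <- list(bundle = b, map = map, pos = pos, neg = neg)
    n_pos_total <- n_pos_total + nrow(pos)
  }
  if (n_pos_total == 0)
    stop(if (mode == "cascade") "no positives survive the cascade filter"
         else "no contacts in the input bundles")
  # subsample the pooled negatives with a single seeded draw
  neg_ids <- unlist(lapply(per_bundle, function(pb) {
    if (nrow(pb$neg)) paste(pb$bundle$id, pb$neg[, 1], pb$neg[, 2], sep = "\r")
    else character(0)
  }), use.names = FALSE)
  n_neg_wanted <- min(length(neg_ids), round(negative_ratio * n_pos_total))
  set.seed(seed)
  chosen <- sample(neg_ids, n_neg_wanted)
  sample_sets <- lapply(per_bundle, function(pb) {
    ids <- strsplit(chosen[startsWith(chosen, paste0(pb$bundle$id, "\r"))], "\r")
    neg <- if (length(ids))
      matrix(as.integer(unlist(lapply(ids, `[`, 2:3))), ncol = 2, byrow = TRUE)
    else matrix(integer(0), ncol = 2)
    pairs <- rbind(pb$pos, neg)
    if (!nrow(pairs)) return(NULL)
    ps <- encode_protein_windows(pb$bundle, config, tables)
    rs <- encode_rna_windows(pb$bundle, config, tables)
    encode_pair(ps, rs, pairs, pb$map)
  })
  bind_samples(Filter(Negate(is.null), sample_sets))
}

#' Grouped cross-validation of the step-3 contact model
#'
#' Within every fold, descriptor tables and the step-1/step-2 models are fitted
#' on the training complexes; the fold's step-3 training set is built from the
#' training complexes ([build_step3_dataset()], gated by the in-sample
#' step-1/2 predictions in cascade mode, as in training-set construction) and
#' the held-out set from the test complexes (gated by their out-of-sample
#' predictions in cascade mode). Metrics are pooled over held-out pairs.
#'
#' @inheritParams cross_validate
#' @param mode `"flat"` or `"cascade"`.
#' @param thresholds Step-1/step-2 gating thresholds (cascade mode).
#' @param negative_ratio Negatives per positive in both fold datasets.
#' @return An `rpi_metrics` with per-fold reports in attribute `"folds"`.
#' @export
cross_validate_step3 <- function(bundles, config = rpi_feature_config(),
                                 k = 5, seed = 1,
                                 mode = c("flat", "cascade"), learner = "rf",
                                 hyperparams = list(),
                                 thresholds = c(0.5, 0.5), negative_ratio = 1,
                                 threshold = 0.5) {
  mode <- match.arg(mode)
  ids <- vapply(bundles, `[[`, character(1), "id")
  folds <- .grouped_folds(ids, k, seed)
  scores <- numeric(0); labels <- logical(0); fold_reports <- list()
  for (f in seq_len(k)) {
    train_b <- bundles[folds != f]
    test_b <- bundles[folds == f]
    tables <- fit_feature_tables(train_b, config)
    enc_p <- lapply(train_b, encode_protein_windows, config = config,
                    tables = tables)
    enc_r <- lapply(train_b, encode_rna_windows, config = config,
                    tables = tables)
    m1 <- train_model(bind_samples(enc_p), learner = learner,
                      hyperparams = hyperparams, seed = seed + f)
    m2 <- train_model(bind_samples(enc_r), learner = learner,
                      hyperparams = hyperparams, seed = seed + f + 1000L)
    score_side <- function(bs, model, encode) {
      out <- lapply(bs, function(b)
        predict(model, encode(b, config = config, tables = tables)))
      names(out) <- vapply(bs, `[[`, character(1), "id")
      out
    }
    s1_tr <- score_side(train_b, m1, encode_protein_windows)
    s2_tr <- score_side(train_b, m2, encode_rna_windows)
    s1_te <- score_side(test_b, m1, encode_protein_windows)
    s2_te <- score_side(test_b, m2, encode_rna_windows)
    tr <- build_step3_dataset(train_b, config, tables, mode,
                              s1_tr, s2_tr, thresholds, negative_ratio,
                              seed = seed + 10L * f)
    te <- build_step3_dataset(test_b, config, tables, mode,
                              s1_te, s2_te, thresholds, negative_ratio,
                              seed = seed + 10L * f + 5L)
    m3 <- train_model(tr, learner = learner, hyperparams = hyperparams,
                      seed = seed + f + 2000L)
    s <- predict(m3, te)
    scores <- c(scores, s); labels <- c(labels, te$labels)
    fold_reports[[f]] <- compute_metrics(s, te$labels, threshold)
  }
  out <- compute_metrics(scores, labels, threshold)
  attr(out, "folds") <- fold_reports
  out
}

#' Fit the full three-model cascade
#'
#' Trains the step-1 (residue), step-2 (nucleotide) and step-3 (pair) models on
#' the given complexes, with the descriptor tables fitted on the same set. The
#' step-3 training set is gated by the in-sample step-1/2 predictions in
#' cascade mode.
#'
#' @inheritParams cross_validate_step3
#' @return Object of class `rpi_cascade`: the three `rpi_model`s, the fitted
#'   tables, the configuration, thresholds and mode.
#' @export
fit_cascade <- function(bundles, config = rpi_feature_config(),
                        mode = c("cascade", "flat"), learner = "rf",
                        hyperparams = list(), thresholds = c(0.5, 0.5),
                        negative_ratio = 1, seed = 1) {
  mode <- match.arg(mode)
  tables <- fit_feature_tables(bundles, config)
  ids <- vapply(bundles, `[[`, character(1), "id")
  m1 <- train_model(bind_samples(lapply(bundles, encode_protein_windows,
                                        config = config, tables = tables)),
                    learner = learner, hyperparams = hyperparams, seed = seed)
  m2 <- train_model(bind_samples(lapply(bundles, encode_rna_windows,
                                        config = config, tables = tables)),
                    learner = learner, hyperparams = hyperparams,
                    seed = seed + 1L)
  s1 <- lapply(bundles, function(b)
    predict(m1, encode_protein_windows(b, config, tables)))
  s2 <- lapply(bundles, function(b)
    predict(m2, encode_rna_windows(b, config, tables)))
  names(s1) <- names(s2) <- ids
  ds3 <- build_step3_dataset(bundles, config, tables, mode, s1, s2,
                             thresholds, negative_ratio, seed = seed + 2L)
  m3 <- train_model(ds3, learner = learner, hyperparams = hyperparams,
                    seed = seed + 3L)
  structure(list(model_step1 = m1, model_step2 = m2, model_step3 = m3,
                 tables = tables, config = config, thresholds = thresholds,
                 mode = mode),
            class = "rpi_cascade")
}

#' Predict binding sites and contacts for one complex
#'
#' Scores every residue (step 1) and nucleotide (step 2); step-3 contact scores
#' are emitted for all residue-nucleotide pairs in flat mode, or only for pairs
#' whose residue and nucleotide pass the step-1/2 thresholds in cascade mode
#' (steps 1-2 scores are always returned in full).
#'
#' @param bundle A bundle of the complex to score (labels not required).
#' @param cascade An `rpi_cascade` from [fit_cascade()].
#' @param mode Override the cascade's mode (`"cascade"` or `"flat"`).
#' @return List with `residue_scores`, `nucleotide_scores`, and `pairs`
#'   (data frame `residue`, `nucleotide`, `score`, sorted by score).
#' @export
cascade_predict <- function(bundle, cascade, mode = cascade$mode) {
  stopifnot(inherits(cascade, "rpi_cascade"))
  mode <- match.arg(mode, c("cascade", "flat"))
  ps <- encode_protein_windows(bundle, cascade$config, cascade$tables)
  rs <- encode_rna_windows(bundle, cascade$config, cascade$tables)
  s1 <- predict(cascade$model_step1, ps)
  s2 <- predict(cascade$model_step2, rs)
  ii <- if (mode == "cascade") which(s1 >= cascade$thresholds[1]) else
    seq_along(s1)
  jj <- if (mode == "cascade") which(s2 >= cascade$thresholds[2]) else
    seq_along(s2)
  pairs <- data.frame(residue = integer(0), nucleotide = integer(0),
                      score = numeric(0))
  if (length(ii) && length(jj)) {
    grid <- as.matrix(expand.grid(residue = ii, nucleotide = jj))
    s3 <- predict(cascade$model_step3, encode_pair(ps, rs, grid)$features)
    pairs <- data.frame(residue = grid[, 1], nucleotide = grid[, 2],
                        score = s3)
    pairs <- pairs[order(-pairs$score, pairs$residue, pairs$nucleotide), ]
    rownames(pairs) <- NULL
  }
  list(residue_scores = s1, nucleotide_scores = s2, pairs = pairs)
}
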