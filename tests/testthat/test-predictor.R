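# small encoded dataset helpers
pred_bundles <- function(seed = 5, n = 8, plen = 40, rlen = 24)
  generate_bundles(strong_planted_spec(seed, n_complexes = n,
                                       protein_length = plen,
                                       rna_length = rlen))

encoded_set <- function(bs, side = "protein", cfg = rpi_feature_config()) {
  tb <- fit_feature_tables(bs, cfg)
  enc <- if (side == "protein") encode_protein_windows else encode_rna_windows
  bind_samples(lapply(bs, enc, config = cfg, tables = tb))
}

test_that("metrics reproduce hand-computed values on a fixed confusion", {
  # TP=3 FP=1 FN=2 TN=4
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.4, 0.1, 0.05, 0.15)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_identical(c(m$TP, m$FP, m$FN, m$TN), c(3L, 1L, 2L, 4L))
  expect_equal(m$SN, 0.6)
  expect_equal(m$SP, 0.8)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$PPV, 0.75)
  expect_equal(m$NPV, 2 / 3, tolerance = 1e-9)
  expect_equal(m$MCC, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6), tolerance = 1e-9)
  # report is internally consistent with its stored confusion
  m2 <- metrics_from_confusion(m$TP, m$FP, m$FN, m$TN)
  for (f in c("SN", "SP", "ACC", "PPV", "NPV", "MCC"))
    expect_equal(m[[f]], m2[[f]])
})

test_that("perfect separation gives unit metrics; single class warns", {
  m <- compute_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(c(m$SN, m$SP, m$ACC, m$MCC, m$AUC), rep(1, 5))
  expect_warning(m1 <- compute_metrics(c(0.2, 0.7), c(TRUE, TRUE)),
                 "AUC undefined")
  expect_true(is.na(m1$AUC))
  expect_equal(m1$SN, 0.5)  # other metrics still computed
})

test_that("rank AUC equals the O(n^2) concordant-pair oracle, ties included", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding => ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    m <- compute_metrics(scores, labels)
    expect_equal(m$AUC, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("training contract: determinism, layout guard, class requirements", {
  bs <- pred_bundles()
  ds <- encoded_set(bs)
  hp <- list(ntree = 60)
  m1 <- train_model(ds, hyperparams = hp, seed = 9)
  m2 <- train_model(ds, hyperparams = hp, seed = 9)
  expect_identical(predict(m1, ds), predict(m2, ds))
  # feature-layout fingerprint refused on mismatch
  swapped <- ds$features[, c(2, 1, 3:ncol(ds$features))]
  expect_error(predict(m1, swapped), "layout mismatch")
  expect_error(train_model(ds$features, rep(TRUE, nrow(ds$features))),
               "both classes")
  expect_error(train_model(ds$features[0, , drop = FALSE], logical(0)),
               "empty")
  # a linearly separable planted set is fit exactly in-sample
  x <- cbind(sig = c(rnorm(60, -3), rnorm(60, 3)), noise = rnorm(120))
  y <- rep(c(FALSE, TRUE), each = 60)
  mf <- train_model(x, y, hyperparams = hp, seed = 1)
  expect_equal(compute_metrics(predict(mf, x), y)$ACC, 1)
})

test_that("alternative learners run behind the same interface", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("nnet")
  bs <- pred_bundles(n = 6)
  ds <- encoded_set(bs)
  for (lrn in c("svm", "nn")) {
    m <- train_model(ds, learner = lrn, seed = 3)
    p <- predict(m, ds)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(compute_metrics(p, ds$labels)$AUC, 0.6)
  }
})

test_that("label shuffling drives CV AUC to chance", {
  bs <- pred_bundles(seed = 6, n = 6)
  aucs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    shuffled <- lapply(bs, function(b) {
      b$protein$labels <- sample(b$protein$labels)
      b
    })
    cv <- cross_validate(shuffled, "protein", k = 3, seed = s,
                         hyperparams = list(ntree = 100))
    cv$AUC
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("grouped CV: fold bookkeeping, leave-one-complex-out, group errors", {
  bs <- pred_bundles(seed = 8, n = 6, plen = 30, rlen = 20)
  cv <- cross_validate(bs, "protein", k = 3, seed = 2,
                       hyperparams = list(ntree = 80))
  folds <- attr(cv, "folds")
  expect_length(folds, 3)
  # pooled confusion equals the sum of per-fold confusions
  for (f in c("TP", "FP", "FN", "TN"))
    expect_identical(sum(vapply(folds, `[[`, integer(1), f)), cv[[f]])
  # k equal to the number of groups = leave-one-complex-out
  cv_loo <- cross_validate(bs, "protein", k = 6, seed = 2,
                           hyperparams = list(ntree = 40))
  expect_length(attr(cv_loo, "folds"), 6)
  expect_error(cross_validate(bs, "protein", k = 7), "fewer groups")
})

test_that("permutation importance: constant group ~0, unknown group rejected", {
  bs <- pred_bundles(seed = 4, n = 6)
  cfg <- rpi_feature_config()
  tb <- fit_feature_tables(bs[1:4], cfg)
  tr <- bind_samples(lapply(bs[1:4], encode_protein_windows, config = cfg,
                            tables = tb))
  te <- bind_samples(lapply(bs[5:6], encode_protein_windows, config = cfg,
                            tables = tb))
  m <- train_model(tr, hyperparams = list(ntree = 150), seed = 1)
  imp <- permutation_importance(m, te, repeats = 5, seed = 1)
  # conservation defaults to a constant column: no information to destroy
  expect_equal(unname(imp["conservation"]), 0, tolerance = 1e-9)
  expect_error(permutation_importance(m, te, groups = list(bogus = 9999)),
               "unknown feature group")
  # two shuffle seeds agree in expectation
  imp2 <- permutation_importance(m, te, repeats = 20, seed = 2)
  imp3 <- permutation_importance(m, te, repeats = 20, seed = 3)
  expect_lt(max(abs(imp2 - imp3)), 2)
})

test_that("step-3 dataset: negative enumeration rule, ratio, cascade filter", {
  # single contact (5,5) on 9-mer chains, radius 2, all neighbours non-binding
  b <- structure(list(
    id = "tiny", class_tag = "other",
    protein = list(seq = strrep("A", 9), plc = paste0("ZZ", strrep("m", 5), "ZZ"),
                   labels = seq_len(9) == 5),
    rna = list(seq = strrep("A", 9), rlc = strrep("b", 9),
               labels = seq_len(9) == 5),
    contacts = contact_map(rbind(c(5, 5)), 9, 9)), class = "rpi_bundle")
  pool <- rpibind:::.negative_pool(rbind(c(5L, 5L)), b$contacts, 2L)
  want <- rbind(c(5, 3), c(5, 4), c(5, 6), c(5, 7),
                c(3, 5), c(4, 5), c(6, 5), c(7, 5))
  expect_setequal(paste(pool[, 1], pool[, 2]), paste(want[, 1], want[, 2]))
  cfg <- rpi_feature_config()
  tb <- fit_feature_tables(list(b), cfg)
  ds <- build_step3_dataset(list(b), cfg, tb, mode = "flat",
                            negative_ratio = 1, seed = 1)
  expect_identical(sum(ds$labels), 1L)
  expect_identical(sum(!ds$labels), 1L)  # ratio 1 exactly when pool suffices
  # all-positive gates make cascade identical to flat
  s1 <- list(tiny = rep(1, 9)); s2 <- list(tiny = rep(1, 9))
  dsc <- build_step3_dataset(list(b), cfg, tb, mode = "cascade",
                             step1_scores = s1, step2_scores = s2,
                             negative_ratio = 1, seed = 1)
  expect_identical(dsc$labels, ds$labels)
  expect_identical(dsc$features, ds$features)
  # gates that kill every positive raise an error
  s0 <- list(tiny = rep(0, 9))
  expect_error(build_step3_dataset(list(b), cfg, tb, mode = "cascade",
                                   step1_scores = s0, step2_scores = s0,
                                   negative_ratio = 1, seed = 1),
               "no positives survive")
})

test_that("cascade gates behave at extreme thresholds and localise the interface", {
  bs <- pred_bundles(seed = 12, n = 7, plen = 30, rlen = 18)
  cfg <- rpi_feature_config()
  cas <- fit_cascade(bs[1:6], cfg, hyperparams = list(ntree = 100), seed = 2)
  target <- bs[[7]]
  # thresholds 0: cascade emits the full pair grid, like flat mode
  cas0 <- cas; cas0$thresholds <- c(0, 0)
  p0 <- cascade_predict(target, cas0, mode = "cascade")
  pf <- cascade_predict(target, cas, mode = "flat")
  expect_identical(nrow(p0$pairs), 30L * 18L)
  expect_setequal(paste(p0$pairs$residue, p0$pairs$nucleotide),
                  paste(pf$pairs$residue, pf$pairs$nucleotide))
  # thresholds 1 + non-degenerate scores: no pairs, side scores still returned
  cas1 <- cas; cas1$thresholds <- c(1.0000001, 1.0000001)
  p1 <- cascade_predict(target, cas1, mode = "cascade")
  expect_identical(nrow(p1$pairs), 0L)
  expect_length(p1$residue_scores, 30L)
  expect_length(p1$nucleotide_scores, 18L)
})

test_that("the top-ranked pair falls inside the planted interface patch", {
  hits <- 0
  for (s in 1:20) {
    bs <- generate_bundles(strong_planted_spec(300 + s, n_complexes = 11,
                                               protein_length = 60,
                                               rna_length = 30))
    cas <- fit_cascade(bs[1:10], rpi_feature_config(),
                       hyperparams = list(ntree = 250), seed = s)
    pred <- cascade_predict(bs[[11]], cas)
    truth <- attr(bs[[11]], "truth")
    hits <- hits + (nrow(pred$pairs) > 0 &&
                      pred$pairs$residue[1] %in% truth$protein_patch &&
                      pred$pairs$nucleotide[1] %in% truth$rna_patch)
  }
  expect_gte(hits, 18)
})
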