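# Classifier layer: training, metrics, grouped cross-validation and
# permutation feature importance for the three prediction steps.

#' Train a binary classifier on encoded samples
#'
#' Random forest by default; support-vector machine and a single-hidden-layer
#' neural network are available behind the same interface for classifier
#' comparisons. The fitted model stores the feature layout and refuses
#' mismatched inputs at prediction time.
#'
#' @param samples An `rpi_samples` object, or a feature matrix.
#' @param labels Logical labels (ignored when `samples` is `rpi_samples`).
#' @param learner `"rf"` (default), `"svm"`, or `"nn"`.
#' @param hyperparams Named list. `rf`: `ntree` (default 500), `mtry` (default
#'   `sqrt(p)`); `svm`: `cost`, `gamma`; `nn`: `size` (default 8), `decay`,
#'   `maxit`.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `rpi_model`.
#' @export
train_model <- function(samples, labels = NULL, learner = c("rf", "svm", "nn"),
                        hyperparams = list(), seed = 1) {
  learner <- match.arg(learner)
  if (inherits(samples, "rpi_samples")) {
    x <- samples$features
    labels <- samples$labels
  } else x <- as.matrix(samples)
  y <- as.logical(labels)
  if (nrow(x) == 0) stop("empty dataset")
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  set.seed(seed)
  fit <- switch(learner,
    rf = randomForest::randomForest(
      x = x, y = yf,
      ntree = hyperparams$ntree %||% 500,
      mtry = hyperparams$mtry %||% max(1, floor(sqrt(ncol(x))))),
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("the 'e1071' package is required for learner = \"svm\"")
      e1071::svm(x = x, y = yf, probability = TRUE,
                 scale = apply(x, 2, stats::sd) > 0,  # skip constant columns
                 cost = hyperparams$cost %||% 1,
                 gamma = hyperparams$gamma %||% (1 / ncol(x)))
    },
    nn = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("the 'nnet' package is required for learner = \"nn\"")
      nnet::nnet(x = x, y = as.numeric(y),
                 size = hyperparams$size %||% 8,
                 decay = hyperparams$decay %||% 0.01,
                 maxit = hyperparams$maxit %||% 200,
                 entropy = TRUE, trace = FALSE)
    })
  structure(list(fit = fit, learner = learner, layout = colnames(x),
                 seed = seed),
            class = "rpi_model")
}

#' Predict positive-class probabilities
#'
#' @param object An `rpi_model`.
#' @param newdata Feature matrix with the layout the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.rpi_model <- function(object, newdata, ...) {
  if (inherits(newdata, "rpi_samples")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$layout))
    stop("feature layout mismatch: model was trained on a different encoding")
  switch(object$learner,
    rf = unname(predict(object$fit, newdata, type = "prob")[, "pos"]),
    svm = {
      pr <- attr(predict(object$fit, newdata, probability = TRUE),
                 "probabilities")
      unname(pr[, "pos"])
    },
    nn = as.numeric(predict(object$fit, newdata))
  )
}

# Metrics -----------------------------------------------------------------------

#' Classification metrics from scores and labels
#'
#' Confusion at the threshold plus SN, SP, ACC, PPV, NPV, MCC and AUC. AUC is
#' the rank (Wilcoxon) statistic with midranks for ties, equivalent to
#' trapezoidal ROC integration. With single-class labels AUC is undefined and
#' returned as `NA` with a warning; the remaining metrics are still computed.
#'
#' @param scores Probabilities in \[0, 1\].
#' @param labels Binary / logical labels.
#' @param threshold Decision threshold (default 0.5); a score >= threshold is
#'   called positive.
#' @return An object of class `rpi_metrics` (a named list).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(scores >= 0 & scores <= 1))
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels); fp <- sum(call_pos & !labels)
  fn <- sum(!call_pos & labels); tn <- sum(!call_pos & !labels)
  metrics_from_confusion(tp, fp, fn, tn,
                         auc = .rank_auc(scores, labels), threshold)
}

.rank_auc <- function(scores, labels) {
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Assemble a metrics report from confusion counts
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @param auc Optional AUC to attach.
#' @param threshold Threshold annotation.
#' @return An `rpi_metrics` object.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn, auc = NA_real_,
                                   threshold = NA_real_) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  structure(list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    SN = safe(tp, tp + fn), SP = safe(tn, tn + fp),
    ACC = safe(tp + tn, tp + fp + fn + tn),
    PPV = safe(tp, tp + fp), NPV = safe(tn, tn + fn),
    MCC = if (mcc_den == 0) NA_real_ else
      (tp * tn - fp * fn) / mcc_den,
    AUC = auc, threshold = threshold
  ), class = "rpi_metrics")
}

#' @export
print.rpi_metrics <- function(x, ...) {
  cat(sprintf(
    "<rpi_metrics> TP=%d FP=%d FN=%d TN=%d\n  SN=%.3f SP=%.3f ACC=%.3f PPV=%.3f NPV=%.3f MCC=%.3f AUC=%s\n",
    x$TP, x$FP, x$FN, x$TN, x$SN, x$SP, x$ACC, x$PPV, x$NPV, x$MCC,
    ifelse(is.na(x$AUC), "NA", sprintf("%.3f", x$AUC))))
  invisible(x)
}

# Cross-validation --------------------------------------------------------------

# fold assignment grouped by complex id
.grouped_folds <- function(ids, k, seed) {
  groups <- unique(ids)
  if (length(groups) < k)
    stop("fewer groups (", length(groups), ") than folds (", k, ")")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(groups)))
  names(fold_of) <- sample(groups)  # shuffle group order too
  unname(fold_of[ids])
}

#' Grouped k-fold cross-validation of a binding-site model
#'
#' Folds are grouped by source complex so that positions of one complex never
#' span training and test folds. Inside every fold the descriptor tables
#' (amino-acid MIP, PLC/RLC triplet log-odds) are refitted on the training
#' complexes only, both sides re-encoded, a model trained, and the held-out
#' complexes scored. Metrics are pooled over the held-out predictions.
#'
#' @param bundles List of labeled bundles.
#' @param side `"protein"` (step 1) or `"rna"` (step 2).
#' @param config An [rpi_feature_config()].
#' @param k Number of folds (>= 2; `k = length(bundles)` gives
#'   leave-one-complex-out).
#' @param seed Integer seed controlling fold assignment and training.
#' @param learner,hyperparams Passed to [train_model()].
#' @param threshold Decision threshold for the pooled confusion.
#' @return An `rpi_metrics` with attributes `folds` (per-fold `rpi_metrics`)
#'   and `scores` (pooled held-out scores and labels).
#' @export
cross_validate <- function(bundles, side = c("protein", "rna"),
                           config = rpi_feature_config(), k = 5, seed = 1,
                           learner = "rf", hyperparams = list(),
                           threshold = 0.5) {
  side <- match.arg(side)
  stopifnot(k >= 2)
  ids <- vapply(bundles, `[[`, character(1), "id")
  folds <- .grouped_folds(ids, k, seed)
  encode <- if (side == "protein") encode_protein_windows else encode_rna_windows
  scores <- numeric(0); labels <- logical(0); fold_reports <- list()
  for (f in seq_len(k)) {
    train_b <- bundles[folds != f]
    test_b <- bundles[folds == f]
    tables <- fit_feature_tables(train_b, config)
    tr <- bind_samples(lapply(train_b, encode, config = config, tables = tables))
    te <- bind_samples(lapply(test_b, encode, config = config, tables = tables))
    model <- train_model(tr, learner = learner, hyperparams = hyperparams,
                         seed = seed + f)
    s <- predict(model, te)
    scores <- c(scores, s); labels <- c(labels, te$labels)
    fold_reports[[f]] <- compute_metrics(s, te$labels, threshold)
  }
  out <- compute_metrics(scores, labels, threshold)
  attr(out, "folds") <- fold_reports
  attr(out, "scores") <- list(scores = scores, labels = labels)
  out
}

# Permutation importance ---------------------------------------------------------

#' Permutation importance of feature families
#'
#' For each named feature group, its columns are shuffled jointly (same row
#' permutation within a repeat) in held-out data and the mean drop in accuracy,
#' in percentage points, over `repeats` shuffles is reported.
#'
#' @param model An `rpi_model`.
#' @param samples Held-out `rpi_samples` (must carry labels).
#' @param groups Named list of column indices; defaults to the sample set's
#'   feature-group slices.
#' @param repeats Number of shuffles per group (default 10).
#' @param seed Integer seed.
#' @param threshold Decision threshold.
#' @return Named numeric vector of mean accuracy drops (percentage points),
#'   with per-repeat values in attribute `"repeats"`.
#' @export
permutation_importance <- function(model, samples, groups = NULL, repeats = 10,
                                   seed = 1, threshold = 0.5) {
  stopifnot(inherits(samples, "rpi_samples"))
  if (is.null(groups)) groups <- samples$groups
  bad <- vapply(groups, function(ix) any(ix < 1 | ix > ncol(samples$features)),
                logical(1))
  if (any(bad)) stop("unknown feature group slice: ",
                     paste(names(groups)[bad], collapse = ", "))
  x <- samples$features
  y <- as.logical(samples$labels)
  base_acc <- mean((predict(model, x) >= threshold) == y)
  set.seed(seed)
  n <- nrow(x)
  drops <- matrix(NA_real_, repeats, length(groups),
                  dimnames = list(NULL, names(groups)))
  for (r in seq_len(repeats)) {
    perm <- sample.int(n)
    for (g in names(groups)) {
      xp <- x
      xp[, groups[[g]]] <- x[perm, groups[[g]], drop = FALSE]
      acc <- mean((predict(model, xp) >= threshold) == y)
      drops[r, g] <- 100 * (base_acc - acc)
    }
  }
  out <- colMeans(drops)
  attr(out, "repeats") <- drops
  out
}
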