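#' Train the random-forest classifier
#'
#' Fits a random forest on a labeled feature matrix and records the
#' feature-name contract, threshold, and pipeline provenance (encoder
#' configuration, selected features, sampling configuration) so that a
#' saved model can re-encode and score raw sequences later.
#'
#' @param fm Labeled feature matrix (see [encode_dataset()]).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param threshold Decision threshold on the positive-vote fraction;
#'   scores at or above it are called positive.
#' @param provenance Optional list describing how `fm` was produced.
#' @return Object of class `protein_classifier`.
#' @export
train_model <- function(fm, n_trees = 100, seed = 1, threshold = 0.5,
                        provenance = list()) {
  p <- fm_parts(fm, require_labels = TRUE)
  if (length(unique(p$y)) < 2) stop("both classes must be present")
  if (nrow(p$X) < 2) stop("need at least 2 samples")
  stopifnot(n_trees >= 1)
  set.seed(as.integer(seed))
  yf <- factor(p$y, levels = LABEL_LEVELS)
  rf <- randomForest::randomForest(p$X, yf, ntree = n_trees)
  structure(
    list(rf = rf, feature_names = colnames(p$X), n_trees = n_trees,
         seed = seed, threshold = threshold, provenance = provenance,
         format_version = 1L),
    class = "protein_classifier")
}

#' @export
print.protein_classifier <- function(x, ...) {
  cat(sprintf("protein_classifier: %d trees, %d features, threshold %.2f\n",
              x$n_trees, length(x$feature_names), x$threshold))
  invisible(x)
}

#' Score samples with a trained classifier
#'
#' The score of a sample is the fraction of trees voting positive; the
#' label is positive iff score >= threshold. The feature columns of `fm`
#' must match the model's stored feature-name contract exactly (order is
#' reconciled by name).
#'
#' @param model A [train_model()] result.
#' @param fm Feature matrix (labels ignored if present).
#' @param sort Sort the report by descending score (screening-report
#'   order)? Default FALSE (input order).
#' @return Data frame with columns `id`, `score`, `label`.
#' @export
predict_score <- function(model, fm, sort = FALSE) {
  stopifnot(inherits(model, "protein_classifier"))
  p <- fm_parts(fm)
  missing <- setdiff(model$feature_names, colnames(p$X))
  extra <- setdiff(colnames(p$X), model$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature names do not match the model contract",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(utils::head(extra, 5),
                                         collapse = ", ")))
  }
  X <- p$X[, model$feature_names, drop = FALSE]
  score <- predict(model$rf, X, type = "prob")[, "positive"]
  out <- data.frame(id = p$ids, score = unname(score),
                    label = ifelse(score >= model$threshold,
                                   "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (sort) out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted Character vectors over
#'   `{"positive", "negative"}`.
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% LABEL_LEVELS), all(predicted %in% LABEL_LEVELS))
  list(tp = sum(truth == "positive" & predicted == "positive"),
       fp = sum(truth == "negative" & predicted == "positive"),
       tn = sum(truth == "negative" & predicted == "negative"),
       fn = sum(truth == "positive" & predicted == "negative"))
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/(TP+TN+FP+FN), and the Matthews correlation coefficient
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). Any metric
#' whose denominator is 0 is reported as 0 by convention and listed in the
#' `degenerate` element.
#'
#' @param counts A [confusion_counts()] list (or any list with tp/fp/tn/fn).
#' @return List with `sn`, `sp`, `acc`, `mcc`, `counts`, `degenerate`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  degen <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { degen <<- c(degen, what); 0 } else num / den
  }
  sn <- safe(tp, tp + fn, "sn")
  sp <- safe(tn, tn + fp, "sp")
  acc <- safe(tp + tn, tp + tn + fp + fn, "acc")
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  list(sn = sn, sp = sp, acc = acc, mcc = mcc,
       counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       degenerate = degen)
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected Mann-Whitney statistic (midranks), which
#' equals the trapezoidal area under the ROC curve traced over all score
#' thresholds, with sensitivity on the y axis and 1 - specificity on x.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Character labels over `{"positive", "negative"}`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% LABEL_LEVELS))
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks correct for ties
  (sum(r[labels == "positive"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report from scores and labels
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels True labels.
#' @param threshold Decision threshold (score >= threshold is positive).
#' @return List of class `metrics_report`: `sn`, `sp`, `acc`, `mcc`,
#'   `auc`, `counts`, `degenerate`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  pred <- ifelse(scores >= threshold, "positive", "negative")
  m <- confusion_metrics(confusion_counts(labels, pred))
  m$auc <- roc_auc(scores, labels)
  m <- m[c("sn", "sp", "acc", "mcc", "auc", "counts", "degenerate")]
  class(m) <- "metrics_report"
  m
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SN %.3f  SP %.3f  ACC %.3f  MCC %.3f  AUC %.3f\n",
              x$sn, x$sp, x$acc, x$mcc, x$auc))
  cat(sprintf("counts: TP %d  FP %d  TN %d  FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  if (length(x$degenerate))
    cat("degenerate (reported as 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the random forest
#'
#' Folds are stratified by class under the given seed. Metrics are computed
#' once on the pooled out-of-fold scores (one confusion matrix), which
#' avoids the small-fold bias of averaging MCC or AUC across folds;
#' `per_fold = TRUE` additionally reports per-fold metrics.
#'
#' @inheritParams train_model
#' @param folds Number of folds (default 5).
#' @param per_fold Also report metrics per fold.
#' @return A `metrics_report` with extra elements `scores` (pooled
#'   out-of-fold scores, input order), `fold_id`, and optionally
#'   `per_fold`.
#' @export
cross_validate <- function(fm, folds = 5, n_trees = 100, seed = 1,
                           threshold = 0.5, per_fold = FALSE) {
  p <- fm_parts(fm, require_labels = TRUE)
  stopifnot(folds >= 2)
  set.seed(as.integer(seed))
  fold_id <- stratified_folds(p$y, folds)
  yf <- factor(p$y, levels = LABEL_LEVELS)
  scores <- numeric(length(p$y))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    fit <- randomForest::randomForest(p$X[!te, , drop = FALSE], yf[!te],
                                      ntree = n_trees)
    scores[te] <- predict(fit, p$X[te, , drop = FALSE],
                          type = "prob")[, "positive"]
  }
  report <- metrics_report(scores, p$y, threshold)
  report$scores <- scores
  report$fold_id <- fold_id
  if (per_fold) {
    report$per_fold <- lapply(seq_len(folds), function(f) {
      te <- fold_id == f
      metrics_report(scores[te], p$y[te], threshold)
    })
  }
  report
}

#' Save / load a trained classifier
#'
#' The archive stores the classifier state together with its provenance
#' and a format version; loading refuses a mismatched version.
#'
#' @param model A `protein_classifier`.
#' @param path Destination path (.rds).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "protein_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "protein_classifier"))
    stop("not a protein_classifier archive")
  if (!identical(model$format_version, 1L))
    stop("unsupported model format version: ", model$format_version)
  model
}
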