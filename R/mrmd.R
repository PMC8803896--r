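#' Max-relevance: absolute Pearson correlation with the class
#'
#' MR_i = |PCC(F_i, C)| where C encodes the class as positive = 1,
#' negative = 0. A zero-variance feature is assigned MR = 0.
#'
#' @param fm Feature matrix with a `label` column (see [encode_dataset()]).
#' @return Named numeric vector of MR values in \[0, 1\].
#' @export
max_relevance <- function(fm) {
  p <- fm_parts(fm, require_labels = TRUE)
  if (length(unique(p$y)) < 2) stop("both classes must be present")
  if (nrow(p$X) < 2) stop("need at least 2 samples")
  cvec <- as.numeric(p$y == "positive")
  mr <- suppressWarnings(abs(as.vector(cor(p$X, cvec))))
  mr[is.na(mr)] <- 0
  setNames(mr, colnames(p$X))
}

# min-max scale columns to [0,1]; constant columns become all-zero
minmax_scale <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
  Xs[, const] <- 0
  Xs
}

# pairwise feature-column distance matrices; zero-norm columns have
# cosine / tanimoto similarity 0 (distance 1) by convention
feature_distances <- function(X) {
  ed <- as.matrix(stats::dist(t(X)))
  G <- crossprod(X)                    # gram matrix of feature columns
  sq <- diag(G)
  nrm <- sqrt(sq)
  cos_den <- outer(nrm, nrm)
  cos_sim <- ifelse(cos_den > 0, G / cos_den, 0)
  tc_den <- outer(sq, sq, "+") - G
  tc_sim <- ifelse(tc_den > 0, G / tc_den, 0)
  list(euclidean = ed, cosine = 1 - cos_sim, tanimoto = 1 - tc_sim)
}

#' Max-distance: mean distance of a feature to all other features
#'
#' MD_i is the mean, over every other feature j, of a distance d(F_i, F_j):
#' euclidean distance, cosine distance (1 - cosine similarity), tanimoto
#' distance (1 - T with T = x.y / (||x||^2 + ||y||^2 - x.y)), or the mean
#' of the three. Feature columns are min-max scaled to \[0, 1\] before
#' distances are taken (switch off with `scale = FALSE`), so that MD is
#' commensurate with MR when the two are summed.
#'
#' @param fm Feature matrix (labels not required).
#' @param method One of `"mean"` (default), `"euclidean"`, `"cosine"`,
#'   `"tanimoto"`.
#' @param scale Min-max scale columns first (default TRUE).
#' @return Named numeric vector of MD values; a lone feature gets MD = 0.
#' @export
max_distance <- function(fm, method = c("mean", "euclidean", "cosine",
                                        "tanimoto"),
                         scale = TRUE) {
  method <- match.arg(method)
  p <- fm_parts(fm)
  X <- if (scale) minmax_scale(p$X) else p$X
  n_feat <- ncol(X)
  if (n_feat == 1L) return(setNames(0, colnames(X)))
  d <- feature_distances(X)
  D <- switch(method,
              euclidean = d$euclidean,
              cosine    = d$cosine,
              tanimoto  = d$tanimoto,
              mean      = (d$euclidean + d$cosine + d$tanimoto) / 3)
  diag(D) <- 0
  setNames(rowSums(D) / (n_feat - 1), colnames(X))
}

#' Rank features by MRMD score
#'
#' Each feature's score is MR_i + MD_i; features are sorted in descending
#' score order. Ties break toward the larger MR, then toward the earlier
#' input column, so the ranking is deterministic.
#'
#' @inheritParams max_relevance
#' @inheritParams max_distance
#' @return A data frame of class `mrmd_ranking` with columns `name`, `mr`,
#'   `md`, `score`, `rank`, ordered by rank.
#' @export
rank_features <- function(fm, method = c("mean", "euclidean", "cosine",
                                         "tanimoto"),
                          scale = TRUE) {
  method <- match.arg(method)
  mr <- max_relevance(fm)
  md <- max_distance(fm, method, scale)
  stopifnot(identical(names(mr), names(md)))
  score <- mr + md
  ord <- order(-score, -mr, seq_along(score))
  out <- data.frame(name = names(score)[ord], mr = unname(mr[ord]),
                    md = unname(md[ord]), score = unname(score[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "distance_method") <- method
  class(out) <- c("mrmd_ranking", "data.frame")
  out
}

#' Accuracy-driven prefix selection over an MRMD ranking
#'
#' Walks down the ranking in prefix sizes `step, 2*step, ...` (the full set
#' is always evaluated), scoring each prefix by stratified k-fold
#' cross-validation accuracy of the random-forest pipeline classifier, and
#' returns the smallest prefix attaining the maximum accuracy ("highest
#' accuracy, fewest features").
#'
#' @param ranking An [rank_features()] result.
#' @param fm The labeled feature matrix the ranking came from.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed; accuracies are reproducible given the seed.
#' @param step Prefix-size increment; `NULL` uses 1 below 100 features and
#'   5 otherwise. `step = 1` reproduces strict one-feature-at-a-time
#'   selection.
#' @param n_trees Forest size used for the prefix evaluations.
#' @return List of class `mrmd_selection`: `sizes`, `accuracies`,
#'   `chosen_size`, `chosen` (feature names), `ranking`.
#' @export
select_subset <- function(ranking, fm, folds = 5, seed = 1, step = NULL,
                          n_trees = 100) {
  stopifnot(inherits(ranking, "mrmd_ranking"), folds >= 2)
  p <- fm_parts(fm, require_labels = TRUE)
  if (nrow(p$X) < folds) stop("fewer samples than folds")
  n_feat <- nrow(ranking)
  step <- step %||% if (n_feat < 100) 1L else 5L
  stopifnot(step >= 1)
  sizes <- unique(c(seq(step, n_feat, by = step), n_feat))

  set.seed(as.integer(seed))
  fold_id <- stratified_folds(p$y, folds)
  acc <- vapply(sizes, function(s) {
    feats <- ranking$name[seq_len(s)]
    cv_accuracy(p$X[, feats, drop = FALSE], p$y, fold_id, n_trees)
  }, numeric(1))

  best <- sizes[which.max(acc)]   # which.max -> first (smallest) maximizer
  structure(
    list(sizes = sizes, accuracies = acc, chosen_size = best,
         chosen = ranking$name[seq_len(best)], ranking = ranking,
         folds = folds, seed = seed, step = step),
    class = "mrmd_selection")
}

#' @export
print.mrmd_selection <- function(x, ...) {
  cat(sprintf("MRMD selection: %d of %d features (CV accuracy %.3f)\n",
              x$chosen_size, nrow(x$ranking), max(x$accuracies)))
  invisible(x)
}

# internal: pooled CV accuracy of a random forest on a fixed fold assignment
cv_accuracy <- function(X, y, fold_id, n_trees) {
  yf <- factor(y, levels = LABEL_LEVELS)
  pred <- character(length(y))
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    fit <- randomForest::randomForest(X[!te, , drop = FALSE], yf[!te],
                                      ntree = n_trees)
    prob <- predict(fit, X[te, , drop = FALSE], type = "prob")[, "positive"]
    pred[te] <- ifelse(prob >= 0.5, "positive", "negative")
  }
  mean(pred == y)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("class '", cls, "' has fewer members (", length(idx),
           ") than folds (", folds, ")")
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}
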