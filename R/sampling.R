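#' Random undersampling of the majority class
#'
#' Rebalances a two-class dataset by discarding a uniform random subset of
#' the majority class, without replacement, down to
#' `round(ratio * minority count)` samples; the minority class is kept
#' intact. With the default `ratio = 1` the classes end up equal in size
#' (e.g. a 1242:568 training set becomes 568:568). If the majority class is
#' already at or below the target, the input is returned unchanged.
#'
#' Works on either a [labeled_dataset()] (sequences) or a feature-matrix
#' data frame with a `label` column: only rows are touched, so
#' undersampling can be applied before feature extraction — the pipeline
#' default order — or after it.
#'
#' @param x A `labeled_dataset` or feature-matrix data frame.
#' @param ratio Target majority:minority ratio after sampling (> 0).
#' @param seed Integer seed; the retained subset is deterministic given the
#'   seed.
#' @return Same type as `x`, with the majority class reduced. Relative
#'   order of retained samples is preserved.
#' @export
random_undersample <- function(x, ratio = 1, seed = 1) {
  stopifnot(ratio > 0)
  labels <- if (inherits(x, "labeled_dataset")) x$labels else {
    if (!is.data.frame(x) || !"label" %in% names(x))
      stop("x must be a labeled_dataset or a feature matrix with labels")
    x$label
  }
  counts <- table(factor(labels, levels = LABEL_LEVELS))
  if (any(counts == 0)) stop("both classes must be present")
  maj <- names(counts)[which.max(counts)]
  n_min <- min(counts)
  target <- round_half_up(ratio * n_min)
  if (target < 1) stop("ratio ", ratio, " implies 0 majority samples")
  if (counts[maj] <= target) return(x)

  set.seed(as.integer(seed))
  maj_idx <- which(labels == maj)
  keep_maj <- sort(sample(maj_idx, target))
  keep <- sort(c(which(labels != maj), keep_maj))

  if (inherits(x, "labeled_dataset")) {
    structure(list(sequences = x$sequences[keep], labels = x$labels[keep]),
              class = "labeled_dataset")
  } else {
    x[keep, , drop = FALSE]
  }
}
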