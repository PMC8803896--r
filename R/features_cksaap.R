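cksaap_pair_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

#' Composition of k-spaced amino-acid pairs (400 features)
#'
#' For a gap k, counts every ordered residue pair (i, j) with i at position
#' p and j at position p + k + 1, over all p in 1..(N-k-1), and normalizes
#' by the number of such pairs, N - k - 1. Pairs are ordered (AC and CA are
#' distinct), giving 20 x 20 = 400 features per gap; the vector sums to 1
#' whenever the sequence admits at least one pair.
#'
#' @param residues Residue string of length N >= k + 2.
#' @param k Non-negative integer gap (number of residues between the pair
#'   members); k = 3 is the pipeline default. Antioxidant-protein studies
#'   found 3-spaced residue pairs particularly informative.
#' @return Named numeric vector of length 400 (names `AA`, `AC`, ..., `YY`,
#'   row-major over the alphabetical alphabet).
#' @export
#' @examples
#' v <- cksaap("ACACA", k = 1)
#' v[v > 0]
cksaap <- function(residues, k = 3) {
  stopifnot(length(k) == 1L, k >= 0, k == as.integer(k))
  idx <- seq_to_index(residues)
  N <- length(idx)
  if (N < k + 2)
    stop(sprintf("sequence length %d < %d (need at least one %d-spaced pair)",
                 N, as.integer(k + 2), as.integer(k)))
  n_pairs <- N - k - 1
  i <- idx[seq_len(n_pairs)]
  j <- idx[seq_len(n_pairs) + k + 1]
  counts <- tabulate((i - 1L) * 20L + j, 400L)
  setNames(counts / n_pairs, cksaap_pair_names())
}

#' Combined 188D + CKSAAP feature vector
#'
#' Concatenates the 188-dimensional descriptor with one 400-dimensional
#' CKSAAP block per requested gap (ascending), for 188 + 400 * length(ks)
#' features in total. The pipeline default, `ks = 3`, yields 588 features.
#'
#' @inheritParams extract_188d
#' @param ks Integer vector of CKSAAP gaps; empty for the plain 188D
#'   descriptor.
#' @return Named numeric vector; CKSAAP names are prefixed `cksaap.k<k>.`.
#' @export
extract_combined <- function(residues, ks = 3,
                             transition_denominator = c("L", "L-1"),
                             groups = NULL) {
  transition_denominator <- match.arg(transition_denominator)
  base <- extract_188d(residues, transition_denominator, groups)
  if (length(ks) == 0L) return(base)
  ks <- sort(as.integer(ks))
  blocks <- lapply(ks, function(k) {
    v <- cksaap(residues, k)
    setNames(v, paste0("cksaap.k", k, ".", names(v)))
  })
  c(base, unlist(blocks))
}

#' Encode a set of sequences as a feature matrix
#'
#' Applies an encoder to every sequence and assembles the results into a
#' data frame with an `id` column, an optional `label` column (when the
#' input is a [labeled_dataset()]), and one named numeric column per
#' feature. This data frame is the interchange format between the encoding,
#' selection, sampling, and classification stages.
#'
#' @param x A [labeled_dataset()] or a named character vector of sequences.
#' @param features One of `"combined"` (188D + CKSAAP, default),
#'   `"188d"`, `"cksaap"`.
#' @param ks CKSAAP gap(s), used by `"combined"` and `"cksaap"`.
#' @inheritParams extract_188d
#' @return Data frame (rows = sequences).
#' @export
encode_dataset <- function(x, features = c("combined", "188d", "cksaap"),
                           ks = 3, transition_denominator = c("L", "L-1"),
                           groups = NULL) {
  features <- match.arg(features)
  transition_denominator <- match.arg(transition_denominator)
  labels <- NULL
  if (inherits(x, "labeled_dataset")) {
    labels <- x$labels
    x <- x$sequences
  }
  stopifnot(is.character(x), length(x) > 0, !is.null(names(x)))
  enc <- switch(features,
    "188d" = function(s) extract_188d(s, transition_denominator, groups),
    "cksaap" = function(s) {
      unlist(lapply(sort(as.integer(ks)), function(k) {
        v <- cksaap(s, k)
        setNames(v, paste0("cksaap.k", k, ".", names(v)))
      }))
    },
    "combined" = function(s)
      extract_combined(s, ks, transition_denominator, groups))
  mat <- t(vapply(x, enc, enc(x[[1]])))
  out <- data.frame(id = names(x), mat, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(labels)) out <- cbind(out[1], label = labels, out[-1])
  out
}

# split a feature-matrix data frame into numeric matrix + labels + ids
fm_parts <- function(fm, require_labels = FALSE) {
  stopifnot(is.data.frame(fm), "id" %in% names(fm))
  has_label <- "label" %in% names(fm)
  if (require_labels && !has_label) stop("feature matrix has no label column")
  feat_cols <- setdiff(names(fm), c("id", "label"))
  if (length(feat_cols) == 0L) stop("feature matrix has no feature columns")
  X <- as.matrix(fm[feat_cols])
  storage.mode(X) <- "double"
  rownames(X) <- fm$id
  list(X = X, y = if (has_label) fm$label else NULL, ids = fm$id)
}

#' Write / read a feature matrix as CSV
#'
#' First column `id`, optional `label`, then named feature columns.
#'
#' @param fm Feature-matrix data frame.
#' @param path CSV path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the data frame.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(fm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(fm)) stop("feature matrix CSV must have an id column")
  if ("label" %in% names(fm)) fm$label <- tolower(fm$label)
  fm
}
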