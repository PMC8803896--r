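#' Read protein sequences from a FASTA file
#'
#' Sequences are returned as a named character vector (ids as names,
#' residue strings as values), uppercased, in file order. Record parsing is
#' delegated to [seqinr::read.fasta()]; this wrapper enforces the dataset
#' contract: a non-empty file, well-formed headers, and unique ids.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased residue strings.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "ggw", "y"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA header at line ", first,
         ": expected '>' before any sequence data")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  bad <- headers[!nzchar(sub("^>\\s*", "", trimws(lines[headers])))]
  if (length(bad)) stop("malformed FASTA header at line ", bad[1L], ": empty id")

  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  ids <- names(recs)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1L])
  seqs <- toupper(unlist(recs, use.names = FALSE))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(nzchar(names(seqs))))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Validate a protein sequence against the 20-letter alphabet
#'
#' A sequence is rejected if it contains any character outside the 20
#' standard amino acids (ambiguity codes B/X/Z, the rare U/O, gaps, stops)
#' or is shorter than `min_length`. This mirrors the hygiene rule used when
#' curating antioxidant-protein training data: ambiguous entries are
#' excluded rather than repaired.
#'
#' @param residues A single residue string (uppercase).
#' @param min_length Minimum acceptable length; pipeline stages that need
#'   longer sequences (e.g. k-spaced pair counting) declare their own
#'   minimum via this argument.
#' @return A list with `accept` (logical) and `reason` (`NULL` when
#'   accepted, otherwise a message naming the first offence).
#' @export
#' @examples
#' validate_sequence("ACDEFGHIK")
#' validate_sequence("ACXDE")$reason
validate_sequence <- function(residues, min_length = 1) {
  stopifnot(is.character(residues), length(residues) == 1L)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", residues)
  if (bad > 0) {
    return(list(accept = FALSE,
                reason = sprintf("nonstandard letter %s at position %d",
                                 substr(residues, bad, bad), bad)))
  }
  if (nchar(residues) < min_length) {
    return(list(accept = FALSE,
                reason = sprintf("length %d < %d", nchar(residues),
                                 as.integer(min_length))))
  }
  list(accept = TRUE, reason = NULL)
}

#' Assemble a labeled two-class sequence dataset
#'
#' @param positive,negative Named character vectors of residue strings
#'   (e.g. from [read_fasta()]). Ids must be unique across both classes.
#' @return An object of class `labeled_dataset`: a list with `sequences`
#'   (named character vector) and `labels` (character, "positive" /
#'   "negative", parallel to `sequences`).
#' @export
labeled_dataset <- function(positive, negative) {
  stopifnot(length(positive) > 0, length(negative) > 0)
  seqs <- c(positive, negative)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("duplicate id ", dup[1L], " across classes")
  structure(
    list(sequences = seqs,
         labels = rep(c("positive", "negative"),
                      c(length(positive), length(negative)))),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences (%d positive, %d negative)\n",
              length(x$sequences), sum(x$labels == "positive"),
              sum(x$labels == "negative")))
  invisible(x)
}

dataset_class <- function(data, label) {
  sel <- data$labels == label
  data$sequences[sel]
}

# round-half-up: ties in the test-set size resolve toward the test set
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split of a labeled dataset
#'
#' Each class is split independently, so a 4:1 split of an imbalanced
#' dataset preserves the class ratio exactly in both parts (e.g. 710
#' positives and 1552 negatives at `test_fraction = 0.2` give a test set of
#' 142 and 310). The test set receives `round(test_fraction * class size)`
#' members per class, ties rounding up.
#'
#' @param data A [labeled_dataset()].
#' @param test_fraction Fraction of each class assigned to the test set,
#'   in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `test`, both `labeled_dataset`s.
#' @export
split_dataset <- function(data, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"),
            test_fraction > 0, test_fraction < 1)
  pos <- dataset_class(data, "positive")
  neg <- dataset_class(data, "negative")
  if (length(pos) < 2 || length(neg) < 2)
    stop("each class needs at least 2 members to split")
  set.seed(as.integer(seed))
  pick <- function(x) {
    n_test <- round_half_up(test_fraction * length(x))
    sort(sample(length(x), n_test))
  }
  ip <- pick(pos); ing <- pick(neg)
  list(train = labeled_dataset(pos[-ip], neg[-ing]),
       test  = labeled_dataset(pos[ip],  neg[ing]))
}

#' Read a label file (CSV with columns id, label)
#'
#' Labels are matched case-insensitively against the vocabulary
#' `{positive, negative}`.
#'
#' @param path CSV path.
#' @return Named character vector of labels ("positive"/"negative").
#' @export
read_labels <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab)))
    stop("label file must have columns id, label")
  lab <- tolower(trimws(tab$label))
  bad <- setdiff(unique(lab), LABEL_LEVELS)
  if (length(bad)) stop("unknown label value: ", bad[1L])
  setNames(lab, tab$id)
}
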