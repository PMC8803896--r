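#' Physicochemical residue grouping tables
#'
#' Eight physicochemical properties (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, surface tension,
#' secondary-structure propensity, solvent accessibility), each
#' partitioning the 20 amino acids into three disjoint groups. These
#' groupings are the classical CTD (composition/transition/distribution)
#' lookup tables; they are shipped as a plain-text table so the encoding is
#' auditable and can be overridden with a custom file of the same format.
#'
#' @param path Optional path to a TSV with columns
#'   `property, group1, group2, group3`; defaults to the table shipped with
#'   the package.
#' @return A data frame with one row per property, columns `property`,
#'   `group1`, `group2`, `group3` (residue strings). The three groups of
#'   every row are validated to partition the 20-letter alphabet.
#' @export
property_groups <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aa_property_groups.tsv",
                                package = "protscreen", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("property", "group1", "group2", "group3") %in% names(tab)))
  for (r in seq_len(nrow(tab))) {
    res <- unlist(strsplit(c(tab$group1[r], tab$group2[r], tab$group3[r]), ""))
    if (anyDuplicated(res) || !setequal(res, AA_ALPHABET))
      stop("groups of property '", tab$property[r],
           "' do not partition the 20-letter alphabet")
  }
  tab
}

.cache <- new.env(parent = emptyenv())

# residue index (1..20 into AA_ALPHABET) -> group index (1..3), one column
# per property; the matrix for the shipped table is computed once and cached
group_index_matrix <- function(groups = NULL) {
  if (is.null(groups)) {
    if (is.null(.cache$gm)) .cache$gm <- group_index_matrix(property_groups())
    return(.cache$gm)
  }
  m <- sapply(seq_len(nrow(groups)), function(r) {
    g <- integer(20)
    for (i in 1:3) {
      res <- strsplit(groups[[paste0("group", i)]][r], "")[[1]]
      g[match(res, AA_ALPHABET)] <- i
    }
    g
  })
  colnames(m) <- groups$property
  m
}

seq_to_index <- function(residues) {
  idx <- match(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains a nonstandard letter; ",
                       "run validate_sequence() first")
  idx
}

#' Amino-acid composition (20 features)
#'
#' Frequency of each residue, n_a / L, in fixed alphabetical order
#' ACDEFGHIKLMNPQRSTVWY. Entries sum to 1.
#'
#' @param residues A residue string over the 20-letter alphabet.
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aac("AACD")
aac <- function(residues) {
  idx <- seq_to_index(residues)
  if (length(idx) == 0L) stop("empty sequence")
  setNames(tabulate(idx, 20) / length(idx), AA_ALPHABET)
}

#' CTD features for one physicochemical property (21 features)
#'
#' Given a 3-group partition of the alphabet, computes:
#' \describe{
#'   \item{content (3)}{group frequency CS_i / L;}
#'   \item{distribution (15)}{for each group, the 1-based positions of the
#'     1st and the 25/50/75/100-percent occurrences of that group's
#'     residues (fractional ranks rounded up), each divided by L; all five
#'     are 0 for a group absent from the sequence;}
#'   \item{transition (3)}{counts of adjacent residue pairs whose members
#'     lie in groups \{1,2\}, \{1,3\}, \{2,3\} (either order), divided by
#'     the sequence length L (the conventional L-1 denominator is
#'     available via `transition_denominator = "L-1"`).}
#' }
#'
#' @param residues Residue string.
#' @param group_idx Either a property name from [property_groups()] or an
#'   integer vector of length 20 mapping each alphabet residue to a group
#'   in 1..3.
#' @param transition_denominator `"L"` (default) or `"L-1"`.
#' @return Named numeric vector of length 21
#'   (`content.g1..g3`, `dist.g<i>.p{1,25,50,75,100}`, `trans.g1g2`,
#'   `trans.g1g3`, `trans.g2g3`).
#' @export
#' @examples
#' ctd_property("RG", "hydrophobicity")
ctd_property <- function(residues, group_idx,
                         transition_denominator = c("L", "L-1")) {
  transition_denominator <- match.arg(transition_denominator)
  if (is.character(group_idx) && length(group_idx) == 1L) {
    gm <- group_index_matrix()
    if (!group_idx %in% colnames(gm)) stop("unknown property: ", group_idx)
    group_idx <- gm[, group_idx]
  }
  stopifnot(length(group_idx) == 20L, all(group_idx %in% 1:3))
  idx <- seq_to_index(residues)
  L <- length(idx)
  if (L == 0L) stop("empty sequence")
  g <- group_idx[idx]

  cs <- tabulate(g, 3)
  content <- cs / L

  dist <- numeric(15)
  for (i in 1:3) {
    if (cs[i] > 0) {
      pos <- which(g == i)
      ranks <- c(1, ceiling(c(0.25, 0.50, 0.75) * cs[i]), cs[i])
      dist[(i - 1) * 5 + 1:5] <- pos[ranks] / L
    }
  }

  trans <- numeric(3)
  if (L >= 2) {
    a <- g[-L]; b <- g[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- c(sum(lo == 1 & hi == 2),
               sum(lo == 1 & hi == 3),
               sum(lo == 2 & hi == 3))
  }
  denom <- if (transition_denominator == "L") L else max(L - 1, 1)
  trans <- trans / denom

  setNames(c(content, dist, trans),
           c(paste0("content.g", 1:3),
             paste0("dist.g", rep(1:3, each = 5), ".p",
                    rep(c(1, 25, 50, 75, 100), 3)),
             c("trans.g1g2", "trans.g1g3", "trans.g2g3")))
}

#' The 188-dimensional composition/physicochemical descriptor
#'
#' Concatenates the 20 amino-acid-composition features with 21 CTD features
#' for each of the eight physicochemical properties (8 x 21 = 168), giving
#' 188 named values, all in \[0, 1\]. Property blocks appear in the order
#' of [property_groups()]: hydrophobicity, van der Waals volume, polarity,
#' polarizability, charge, surface tension, secondary structure, solvent
#' accessibility.
#'
#' @inheritParams ctd_property
#' @param groups Optional grouping table in the format of
#'   [property_groups()]; `NULL` uses the shipped table.
#' @return Named numeric vector of length 188 (names `aac.A`, ...,
#'   `hydrophobicity.content.g1`, ..., `solvent_accessibility.trans.g2g3`).
#' @export
#' @examples
#' length(extract_188d("ACDEFGHIKLMNPQRSTVWY"))
extract_188d <- function(residues, transition_denominator = c("L", "L-1"),
                         groups = NULL) {
  transition_denominator <- match.arg(transition_denominator)
  gm <- group_index_matrix(groups)
  blocks <- lapply(colnames(gm), function(p) {
    v <- ctd_property(residues, gm[, p],
                      transition_denominator = transition_denominator)
    setNames(v, paste0(p, ".", names(v)))
  })
  a <- aac(residues)
  c(setNames(a, paste0("aac.", names(a))), unlist(blocks))
}
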