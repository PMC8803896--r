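# Independent brute-force oracles. Everything here is written as plain
# position-by-position loops, deliberately sharing no code with the package.

ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(L) paste(sample(ALPHA, L, replace = TRUE), collapse = "")

# grouping rows as shipped (hard-coded; independent of the package's table)
ORACLE_GROUPS <- list(
  hydrophobicity        = c("RKEDQN", "GASTPHY", "CVLIMFW"),
  vdw_volume            = c("GASCTPD", "NVEQIL", "MHKFRYW"),
  polarity              = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability        = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge                = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  surface_tension       = c("GQDNAHR", "KTSEC", "ILMFPWYV"),
  secondary_structure   = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_accessibility = c("ALFCGIVW", "RKQEND", "MPSTHY"))

naive_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- numeric(20)
  for (i in 1:20) {
    for (c in ch) if (c == ALPHA[i]) out[i] <- out[i] + 1
  }
  out / length(ch)
}

# 21 CTD features for one property: content(3), distribution(15), transition(3)
naive_ctd <- function(s, groups, denom = "L") {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  grp <- integer(L)
  for (p in seq_len(L)) {
    for (i in 1:3) {
      if (grepl(ch[p], groups[i], fixed = TRUE)) grp[p] <- i
    }
  }
  content <- numeric(3)
  for (i in 1:3) content[i] <- sum(grp == i) / L
  dist <- numeric(15)
  for (i in 1:3) {
    pos <- which(grp == i)
    cs <- length(pos)
    if (cs > 0) {
      ranks <- c(1, ceiling(0.25 * cs), ceiling(0.50 * cs),
                 ceiling(0.75 * cs), cs)
      dist[(i - 1) * 5 + 1:5] <- pos[ranks] / L
    }
  }
  trans <- numeric(3)
  if (L >= 2) {
    for (p in 1:(L - 1)) {
      pair <- sort(c(grp[p], grp[p + 1]))
      if (pair[1] == 1 && pair[2] == 2) trans[1] <- trans[1] + 1
      if (pair[1] == 1 && pair[2] == 3) trans[2] <- trans[2] + 1
      if (pair[1] == 2 && pair[2] == 3) trans[3] <- trans[3] + 1
    }
  }
  trans <- trans / if (denom == "L") L else (L - 1)
  c(content, dist, trans)
}

naive_188d <- function(s, denom = "L") {
  out <- naive_aac(s)
  for (g in ORACLE_GROUPS) out <- c(out, naive_ctd(s, g, denom))
  unname(out)
}

naive_cksaap <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  N <- length(ch)
  counts <- matrix(0, 20, 20, dimnames = list(ALPHA, ALPHA))
  for (p in 1:(N - k - 1)) counts[ch[p], ch[p + k + 1]] <-
      counts[ch[p], ch[p + k + 1]] + 1
  as.vector(t(counts)) / (N - k - 1)
}

# --- MRMD oracles ----------------------------------------------------------

naive_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  den <- sqrt(sum(xm^2) * sum(ym^2))
  if (den == 0) return(0)
  sum(xm * ym) / den
}

naive_minmax <- function(x) {
  if (max(x) == min(x)) return(rep(0, length(x)))
  (x - min(x)) / (max(x) - min(x))
}

# per-feature MR, MD and score by explicit double loops
naive_mrmd <- function(X, y, method) {
  cvec <- as.numeric(y == "positive")
  n <- ncol(X)
  Xs <- X
  for (j in 1:n) Xs[, j] <- naive_minmax(X[, j])
  mr <- md <- numeric(n)
  for (i in 1:n) {
    mr[i] <- abs(naive_pearson(X[, i], cvec))
    acc <- 0
    for (j in setdiff(1:n, i)) {
      a <- Xs[, i]; b <- Xs[, j]
      ed <- sqrt(sum((a - b)^2))
      dot <- sum(a * b)
      na2 <- sum(a^2); nb2 <- sum(b^2)
      cos_d <- 1 - (if (na2 > 0 && nb2 > 0) dot / sqrt(na2 * nb2) else 0)
      tc_den <- na2 + nb2 - dot
      tc_d <- 1 - (if (tc_den > 0) dot / tc_den else 0)
      acc <- acc + switch(method,
                          euclidean = ed, cosine = cos_d, tanimoto = tc_d,
                          mean = (ed + cos_d + tc_d) / 3)
    }
    md[i] <- acc / (n - 1)
  }
  list(mr = mr, md = md, score = mr + md)
}

# --- evaluation oracles ----------------------------------------------------

naive_metrics <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "positive" && pred[i] == "positive") tp <- tp + 1
    if (truth[i] == "negative" && pred[i] == "positive") fp <- fp + 1
    if (truth[i] == "negative" && pred[i] == "negative") tn <- tn + 1
    if (truth[i] == "positive" && pred[i] == "negative") fn <- fn + 1
  }
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  list(sn = if (tp + fn > 0) tp / (tp + fn) else 0,
       sp = if (tn + fp > 0) tn / (tn + fp) else 0,
       acc = (tp + tn) / (tp + tn + fp + fn),
       mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

# pairwise Mann-Whitney: wins + half-ties over all pos/neg pairs
naive_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) tot <- tot + 1
      else if (p == q) tot <- tot + 0.5
    }
  }
  tot / (length(pos) * length(neg))
}
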