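# small labeled feature matrix builder
toy_fm <- function(X, y = NULL) {
  df <- data.frame(id = paste0("s", seq_len(nrow(X))), X, check.names = FALSE)
  if (!is.null(y)) df <- cbind(df[1], label = y, df[-1])
  df
}

test_that("max-relevance is |Pearson| with the 0/1 class and 0 for constants", {
  y <- c("positive", "positive", "negative", "negative")
  X <- cbind(lab = c(1, 1, 0, 0), inv = c(0, 0, 1, 1), const = c(2, 2, 2, 2))
  mr <- max_relevance(toy_fm(X, y))
  expect_equal(unname(mr["lab"]), 1)
  expect_equal(unname(mr["inv"]), 1)     # absolute value
  expect_equal(unname(mr["const"]), 0)   # zero-variance convention
  expect_error(max_relevance(toy_fm(X, rep("positive", 4))), "both classes")
})

test_that("max-relevance is invariant under increasing affine transforms", {
  set.seed(21)
  y <- sample(c("positive", "negative"), 30, replace = TRUE, prob = c(.5, .5))
  x <- rnorm(30)
  m1 <- max_relevance(toy_fm(cbind(f = x), y))
  m2 <- max_relevance(toy_fm(cbind(f = 3.7 * x + 11), y))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("max-distance hand cases: identical columns and the sqrt(2) pair", {
  X <- cbind(a = c(0, 1), b = c(0, 1))
  expect_equal(unname(max_distance(toy_fm(X), "euclidean")), c(0, 0))
  X <- cbind(a = c(0, 1), b = c(1, 0))
  expect_equal(unname(max_distance(toy_fm(X), "euclidean")),
               c(sqrt(2), sqrt(2)))
  # mean method is the average of the three distances
  set.seed(22)
  X <- matrix(runif(60), 15, 4, dimnames = list(NULL, letters[1:4]))
  fm <- toy_fm(X)
  expect_equal(max_distance(fm, "mean"),
               (max_distance(fm, "euclidean") + max_distance(fm, "cosine") +
                max_distance(fm, "tanimoto")) / 3,
               tolerance = 1e-12)
  # a lone feature has no peers
  expect_equal(unname(max_distance(toy_fm(X[, 1, drop = FALSE]))), 0)
})

test_that("MR, MD and scores match the double-loop oracle on random matrices", {
  set.seed(23)
  for (method in c("euclidean", "cosine", "tanimoto", "mean")) {
    X <- matrix(runif(30 * 8), 30, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    X[, 8] <- 0.3                       # include a constant column
    y <- rep(c("positive", "negative"), 15)
    oracle <- naive_mrmd(X, y, method)
    mr <- max_relevance(toy_fm(X, y))
    md <- max_distance(toy_fm(X), method)
    expect_equal(unname(mr), oracle$mr, tolerance = 1e-10)
    expect_equal(unname(md), oracle$md, tolerance = 1e-10)
    rk <- rank_features(toy_fm(X, y), method)
    expect_equal(rk$score[match(paste0("f", 1:8), rk$name)], oracle$score,
                 tolerance = 1e-10)
  }
})

test_that("a label-copy feature outranks uncorrelated noise", {
  set.seed(24)
  y <- rep(c("positive", "negative"), each = 10)
  X <- cbind(signal = as.numeric(y == "positive"),
             matrix(runif(20 * 5), 20, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  rk <- rank_features(toy_fm(X, y))
  expect_identical(rk$name[1], "signal")
})

test_that("ranking is deterministic: ties fall back to MR then input order", {
  y <- rep(c("positive", "negative"), 4)
  X <- cbind(a = rep(1, 8), b = rep(1, 8), c = rep(1, 8))
  rk <- rank_features(toy_fm(X, y))
  expect_identical(rk$name, c("a", "b", "c"))   # all scores equal
  expect_equal(length(unique(rk$score)), 1)

  # permuting columns permutes ranks but not per-name scores
  set.seed(25)
  X <- matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  y <- rep(c("positive", "negative"), 5)
  r1 <- rank_features(toy_fm(X, y))
  r2 <- rank_features(toy_fm(X[, c(3, 1, 4, 2)], y))
  expect_equal(r2$score[match(r1$name, r2$name)], r1$score, tolerance = 1e-12)
})

test_that("subset selection keeps the smallest prefix at peak CV accuracy", {
  set.seed(26)
  y <- rep(c("positive", "negative"), each = 20)
  X <- cbind(perfect = as.numeric(y == "positive") + runif(40, 0, 0.01),
             matrix(runif(40 * 6), 40, 6,
                    dimnames = list(NULL, paste0("noise", 1:6))))
  fm <- toy_fm(X, y)
  rk <- rank_features(fm)
  expect_identical(rk$name[1], "perfect")
  sel <- select_subset(rk, fm, folds = 5, seed = 1, step = 1, n_trees = 40)
  expect_equal(sel$chosen_size, 1)
  expect_identical(sel$chosen, "perfect")
  expect_equal(max(sel$accuracies), 1)

  # degenerate stepping: one evaluation over the full set
  sel_full <- select_subset(rk, fm, folds = 5, seed = 1, step = ncol(X),
                            n_trees = 40)
  expect_identical(sel_full$sizes, ncol(X))
  expect_identical(sel_full$chosen, rk$name)

  # reproducibility of the accuracy trace, and chosen >= full-set accuracy
  sel2 <- select_subset(rk, fm, folds = 5, seed = 1, step = 1, n_trees = 40)
  expect_identical(sel$accuracies, sel2$accuracies)
  expect_gte(max(sel$accuracies), sel$accuracies[length(sel$accuracies)])
})

test_that("selection refuses more folds than samples", {
  y <- rep(c("positive", "negative"), 2)
  fm <- toy_fm(cbind(f = 1:4), y)
  rk <- rank_features(fm)
  expect_error(select_subset(rk, fm, folds = 5, seed = 1), "fewer")
})
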