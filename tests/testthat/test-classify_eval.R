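# separable toy feature matrix: one informative dimension plus noise
separable_fm <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c("positive", "negative"), each = n_per_class)
  X <- cbind(sig = ifelse(y == "positive", 1, 0) + rnorm(2 * n_per_class, 0, 0.05),
             noise = runif(2 * n_per_class))
  data.frame(id = paste0("s", seq_along(y)), label = y, X,
             check.names = FALSE)
}

test_that("confusion metrics evaluate the closed forms exactly", {
  m <- confusion_metrics(list(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(unlist(m[c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))

  m <- confusion_metrics(list(tp = 5, fn = 5, tn = 5, fp = 5))
  expect_equal(unlist(m[c("sn", "sp", "acc", "mcc")]),
               c(sn = 0.5, sp = 0.5, acc = 0.5, mcc = 0))

  m <- confusion_metrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m$mcc, 70 / sqrt(9900), tolerance = 1e-12)
  expect_equal(m$sn, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.85)
})

test_that("zero denominators yield 0 by convention and are flagged", {
  m <- confusion_metrics(list(tp = 0, fn = 0, tn = 7, fp = 3))
  expect_equal(m$sn, 0)
  expect_equal(m$mcc, 0)
  expect_true(all(c("sn", "mcc") %in% m$degenerate))
})

test_that("metrics agree with an independent re-derivation on fuzzed pairs", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:60, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    m <- confusion_metrics(confusion_counts(truth, pred))
    o <- naive_metrics(truth, pred)
    expect_equal(m[c("sn", "sp", "acc", "mcc")], o, tolerance = 1e-12)
    cnt <- m$counts
    expect_equal(cnt$tp + cnt$fp + cnt$tn + cnt$fn, n)
    # ACC identity: class-size weighted mean of SN and SP (when defined)
    P <- cnt$tp + cnt$fn; N <- cnt$tn + cnt$fp
    if (P > 0 && N > 0)
      expect_equal(m$acc, (m$sn * P + m$sp * N) / (P + N), tolerance = 1e-12)
  }
})

test_that("AUC matches hand cases and the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(0.9, 0.1), c("positive", "negative")), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5), c("positive", "negative", "positive")),
               0.5)
  expect_equal(roc_auc(c(0.8, 0.6, 0.4, 0.2),
                       c("positive", "negative", "positive", "negative")),
               0.75)
  expect_error(roc_auc(c(0.2, 0.8), c("positive", "positive")), "both classes")

  set.seed(32)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)         # coarse scores force ties
    expect_equal(roc_auc(scores, labels), naive_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(33)
  labels <- rep(c("positive", "negative"), 10)
  scores <- runif(20)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3, labels), a, tolerance = 1e-12)
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  labels <- sample(c("positive", "negative"), 50, replace = TRUE)
  scores <- round(runif(50), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("training memorizes separable data and is seed-deterministic", {
  fm <- separable_fm()
  model <- train_model(fm, n_trees = 50, seed = 3)
  pred <- predict_score(model, fm)
  expect_identical(pred$label, fm$label)
  model2 <- train_model(fm, n_trees = 50, seed = 3)
  probe <- separable_fm(10, seed = 99)
  expect_identical(predict_score(model2, probe), predict_score(model, probe))
  # degenerate forest size is accepted
  expect_s3_class(train_model(fm, n_trees = 1, seed = 1),
                  "protein_classifier")
  expect_error(train_model(fm[fm$label == "positive", ], n_trees = 5),
               "both classes")
})

test_that("prediction enforces the feature-name contract and the tie rule", {
  fm <- separable_fm()
  model <- train_model(fm, n_trees = 50, seed = 3)
  bad <- fm; names(bad)[names(bad) == "noise"] <- "other"
  expect_error(predict_score(model, bad), "missing: noise")
  expect_error(predict_score(model, bad), "extra: other")

  # scores at exactly the threshold are called positive
  model$threshold <- 0
  pred <- predict_score(model, fm)
  expect_true(all(pred$label == "positive"))

  # screening-report ordering
  pred <- predict_score(model, fm, sort = TRUE)
  expect_false(is.unsorted(rev(pred$score)))
})

test_that("cross-validation pools out-of-fold scores and is reproducible", {
  fm <- separable_fm(25, seed = 5)
  cv1 <- cross_validate(fm, folds = 5, n_trees = 50, seed = 11)
  cv2 <- cross_validate(fm, folds = 5, n_trees = 50, seed = 11)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1[c("sn", "sp", "acc", "mcc", "auc")],
                   cv2[c("sn", "sp", "acc", "mcc", "auc")])
  expect_gt(cv1$acc, 0.9)                 # separable data
  # pooled metrics recompute from the pooled scores
  expect_equal(unclass(cv1)[c("sn", "sp", "acc", "mcc", "auc")],
               unclass(metrics_report(cv1$scores, fm$label))[
                 c("sn", "sp", "acc", "mcc", "auc")])
  # per-fold reporting covers every fold
  cvf <- cross_validate(fm, folds = 5, n_trees = 20, seed = 11,
                        per_fold = TRUE)
  expect_length(cvf$per_fold, 5)
  expect_error(cross_validate(separable_fm(3), folds = 5), "fewer members")
})

test_that("label-permuted data scores near chance", {
  set.seed(35)
  fm <- separable_fm(30, seed = 6)
  fm$label <- sample(fm$label)
  cv <- cross_validate(fm, folds = 5, n_trees = 50, seed = 12)
  expect_gt(cv$acc, 0.3)
  expect_lt(cv$acc, 0.7)
  expect_lt(abs(cv$mcc), 0.35)
})

test_that("model archives round-trip and refuse foreign versions", {
  fm <- separable_fm()
  model <- train_model(fm, n_trees = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  loaded <- load_model(f)
  expect_identical(predict_score(loaded, fm), predict_score(model, fm))
  model$format_version <- 99L
  save_model(model, f)
  expect_error(load_model(f), "format version")
})
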