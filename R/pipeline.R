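#' Pipeline configuration
#'
#' Defaults follow the pipeline's reference configuration: combined
#' 188D + CKSAAP(k = 3) features, random undersampling to a 1:1 class
#' ratio applied before feature extraction and selection, MRMD ranking
#' with the mean distance method, 5-fold cross-validation, a 100-tree
#' forest, and a 0.5 decision threshold.
#'
#' @param features `"combined"`, `"188d"`, or `"cksaap"`.
#' @param ks CKSAAP gap(s).
#' @param transition_denominator `"L"` or `"L-1"` (see [ctd_property()]).
#' @param mrmd_method MRMD distance method (see [max_distance()]).
#' @param mrmd_step Prefix-size increment for [select_subset()]; `NULL`
#'   for the adaptive default.
#' @param select Run MRMD subset selection (`TRUE`) or keep all features.
#' @param sample_ratio Majority:minority ratio for undersampling; `NULL`
#'   disables rebalancing.
#' @param sample_before_selection Undersample before feature
#'   extraction/selection (default) or after selection, for ablation.
#' @param n_trees,folds,threshold Classifier and CV settings.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(features = "combined", ks = 3,
                            transition_denominator = "L",
                            mrmd_method = "mean", mrmd_step = NULL,
                            select = TRUE, sample_ratio = 1,
                            sample_before_selection = TRUE,
                            n_trees = 100, folds = 5, threshold = 0.5,
                            seed = 1) {
  structure(list(features = features, ks = ks,
                 transition_denominator = transition_denominator,
                 mrmd_method = mrmd_method, mrmd_step = mrmd_step,
                 select = select, sample_ratio = sample_ratio,
                 sample_before_selection = sample_before_selection,
                 n_trees = n_trees, folds = folds, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, offset)
  as.integer((as.numeric(config$seed) * 101 + offset) %% 2147483647)

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[protscreen] %s | %s",
                              format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full classification pipeline
#'
#' Stages, in order: read and validate the two FASTA inputs, hold out a
#' stratified test fraction, undersample the training majority class,
#' encode features, rank and select features by MRMD, cross-validate the
#' random forest on the training set, train the final model, and evaluate
#' it on the held-out test set. Every stage seed derives from
#' `config$seed`, and the emitted `config.json` snapshot is sufficient to
#' reproduce the run exactly.
#'
#' Artifacts written to `out_dir`: `config.json`, `features.csv`,
#' `ranking.csv`, `selection.json` (when selection runs), `model.rds`,
#' `cv_metrics.json`, `test_metrics.json` (when a test split is held out).
#'
#' @param positive_fasta,negative_fasta FASTA paths for the two classes.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts; `NULL` to skip writing.
#' @param test_fraction Held-out fraction per class (default 0.2); `NULL`
#'   trains on everything and skips the test evaluation.
#' @param min_length Minimum sequence length; defaults to max(ks) + 2 so
#'   every retained sequence supports the largest CKSAAP gap in use.
#' @param quiet Suppress stage logging.
#' @return List with `model`, `cv` (training-set CV `metrics_report`),
#'   `test` (test-set `metrics_report` or `NULL`), `ranking`, `selection`,
#'   `config`, and the retained dataset sizes.
#' @export
run_pipeline <- function(positive_fasta, negative_fasta,
                         config = pipeline_config(), out_dir = NULL,
                         test_fraction = 0.2, min_length = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  min_length <- min_length %||%
    (if (config$features == "188d") 1L else max(config$ks) + 2L)

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_stage(quiet, "%s done (%.1fs)", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  data <- run_stage("read", {
    pos <- read_fasta(positive_fasta)
    neg <- read_fasta(negative_fasta)
    keep <- function(seqs) {
      ok <- vapply(seqs, function(s) validate_sequence(s, min_length)$accept,
                   logical(1))
      seqs[ok]
    }
    pos <- keep(pos); neg <- keep(neg)
    if (!length(pos) || !length(neg))
      stop("no valid sequences left in one of the classes")
    labeled_dataset(pos, neg)
  })

  split <- NULL
  train_data <- data
  if (!is.null(test_fraction)) {
    split <- run_stage("split", split_dataset(data, test_fraction,
                                              seed = stage_seed(config, 1)))
    train_data <- split$train
  }

  if (!is.null(config$sample_ratio) && config$sample_before_selection) {
    train_data <- run_stage("undersample",
      random_undersample(train_data, config$sample_ratio,
                         seed = stage_seed(config, 2)))
  }

  fm <- run_stage("extract",
    encode_dataset(train_data, features = config$features, ks = config$ks,
                   transition_denominator = config$transition_denominator))

  ranking <- run_stage("rank", rank_features(fm, method = config$mrmd_method))
  selection <- NULL
  if (isTRUE(config$select)) {
    selection <- run_stage("select",
      select_subset(ranking, fm, folds = config$folds,
                    seed = stage_seed(config, 3), step = config$mrmd_step,
                    n_trees = config$n_trees))
    fm <- fm[c(intersect(c("id", "label"), names(fm)), selection$chosen)]
  }

  if (!is.null(config$sample_ratio) && !config$sample_before_selection) {
    fm <- run_stage("undersample",
      random_undersample(fm, config$sample_ratio,
                         seed = stage_seed(config, 2)))
  }

  cv <- run_stage("cv",
    cross_validate(fm, folds = config$folds, n_trees = config$n_trees,
                   seed = stage_seed(config, 4),
                   threshold = config$threshold))

  model <- run_stage("train",
    train_model(fm, n_trees = config$n_trees, seed = stage_seed(config, 5),
                threshold = config$threshold,
                provenance = list(
                  features = config$features, ks = config$ks,
                  transition_denominator = config$transition_denominator,
                  selected = if (is.null(selection)) NULL else selection$chosen,
                  sample_ratio = config$sample_ratio,
                  seed = config$seed)))

  test <- NULL
  if (!is.null(split)) {
    test <- run_stage("evaluate", {
      scored <- pipeline_predict(model, split$test$sequences, sort = FALSE)
      metrics_report(scored$score, split$test$labels, config$threshold)
    })
  }

  result <- list(model = model, cv = cv, test = test, ranking = ranking,
                 selection = selection, config = config,
                 n_train = length(train_data$sequences),
                 n_test = if (is.null(split)) 0L
                          else length(split$test$sequences))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    write_feature_matrix(fm, file.path(out_dir, "features.csv"))
    write.csv(as.data.frame(ranking), file.path(out_dir, "ranking.csv"),
              row.names = FALSE)
    if (!is.null(selection))
      jsonlite::write_json(
        list(sizes = selection$sizes, accuracies = selection$accuracies,
             chosen_size = selection$chosen_size, chosen = selection$chosen,
             seed = selection$seed, step = selection$step),
        file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    save_model(model, file.path(out_dir, "model.rds"))
    write_metrics_json(cv, file.path(out_dir, "cv_metrics.json"))
    if (!is.null(test))
      write_metrics_json(test, file.path(out_dir, "test_metrics.json"))
  }
  result
}

write_metrics_json <- function(m, path) {
  jsonlite::write_json(
    list(sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc, auc = m$auc,
         counts = m$counts, degenerate = m$degenerate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score raw sequences with a pipeline-trained model
#'
#' Re-encodes the sequences according to the encoder configuration stored
#' in the model's provenance, restricts to the model's selected features,
#' and returns the screening report sorted by descending score — the
#' virtual-screening workflow (e.g. ranking candidate drug-target enzymes
#' by predicted probability of the target property).
#'
#' @param model A `protein_classifier` trained by [run_pipeline()] (its
#'   provenance must carry the encoder configuration).
#' @param seqs Named character vector of residue strings, or a
#'   [labeled_dataset()].
#' @param sort Sort descending by score (default TRUE).
#' @return Data frame `id`, `score`, `label`.
#' @export
pipeline_predict <- function(model, seqs, sort = TRUE) {
  stopifnot(inherits(model, "protein_classifier"))
  pv <- model$provenance
  if (is.null(pv$features))
    stop("model provenance lacks the encoder configuration")
  if (inherits(seqs, "labeled_dataset")) seqs <- seqs$sequences
  fm <- encode_dataset(seqs, features = pv$features, ks = pv$ks,
                       transition_denominator = pv$transition_denominator)
  if (!is.null(pv$selected)) fm <- fm[c("id", pv$selected)]
  predict_score(model, fm, sort = sort)
}
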