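#' Read a pipeline configuration from YAML
#'
#' Recognized blocks: `preprocess` (keys `log_base`, `pseudocount`,
#' `variance_drop_fraction`, `correlation_max`, `labeling_scheme`),
#' `stacking` (`n_outer`, `n_inner`, `n_repetitions`, `integrator`,
#' `preset`), `learners` (list of `key` entries with optional `enabled`
#' flag and hyperparameter overrides) and a global `seed`.
#'
#' @param path YAML file.
#' @return List with elements `config` (a [stack_config()]) and
#'   `preprocess` (arguments for [preprocess_dataset()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  registry <- default_registry()
  for (entry in cfg$learners %||% list()) {
    key <- entry$key
    if (is.null(key) || !key %in% names(registry)) stop("unknown learner key in config: ", key)
    if (isFALSE(entry$enabled)) {
      registry[[key]] <- NULL
    } else {
      pars <- entry[setdiff(names(entry), c("key", "enabled"))]
      registry[[key]]$params <- modifyList(registry[[key]]$params, pars)
    }
  }
  st <- cfg$stacking %||% list()
  config <- stack_config(
    n_outer = st$n_outer %||% 10,
    n_inner = st$n_inner %||% 10,
    n_repetitions = st$n_repetitions %||% 10,
    integrator = st$integrator %||% "random_forest",
    labeling_scheme = (cfg$preprocess %||% list())$labeling_scheme %||% "tercile",
    registry = registry,
    preset = st$preset,
    seed = cfg$seed %||% 1
  )
  pp <- cfg$preprocess %||% list()
  preprocess <- list(log_base = pp$log_base %||% 10,
                     pseudocount = pp$pseudocount %||% 1,
                     variance_drop_fraction = pp$variance_drop_fraction %||% 0.5,
                     correlation_max = pp$correlation_max %||% 0.95)
  list(config = config, preprocess = preprocess)
}

#' Run the pipeline on a fixture directory and write result files
#'
#' Reads the dataset, applies the preprocessing cascade, runs
#' [run_stacked_cv()] and writes `predictions.csv` (sample, repetition,
#' probability, producing outer fold), `prediction_matrix.csv` (each
#' labeled sample's test-fold first-level probabilities, repetition 1),
#' `combination_importance.csv` and `metrics.json`.
#'
#' @param data_dir Fixture directory readable by [read_fixture()].
#' @param drug Drug name.
#' @param config A [stack_config()].
#' @param preprocess Argument list for [preprocess_dataset()].
#' @param out_dir Output directory.
#' @return The `stacked_result`, invisibly.
#' @export
run_pipeline <- function(data_dir, drug, config = stack_config(),
                         preprocess = list(), out_dir = ".") {
  dataset <- read_fixture(data_dir)
  dataset <- do.call(preprocess_dataset, c(list(dataset), preprocess))
  t0 <- Sys.time()
  result <- run_stacked_cv(dataset, drug, config)
  message(sprintf("stacked CV for %s: %.1f s", drug,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fold_of <- fold_of_sample(result)
  preds <- do.call(rbind, lapply(seq_len(ncol(result$per_repetition)), function(r) {
    data.frame(sample_id = result$sample_ids, repetition = r,
               probability = result$per_repetition[, r],
               outer_fold = fold_of[, r], stringsAsFactors = FALSE)
  }))
  write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)

  pm <- test_prediction_matrix(result, repetition = 1)
  write.csv(data.frame(sample_id = rownames(pm), pm, check.names = FALSE),
            file.path(out_dir, "prediction_matrix.csv"), row.names = FALSE)

  ci <- result$combination_importance
  write.csv(data.frame(combination = names(ci), importance = ci,
                       row.names = NULL),
            file.path(out_dir, "combination_importance.csv"), row.names = FALSE)

  report <- evaluation_report(result, tissue = attr(dataset, "tissue") %||% NULL)
  jsonlite::write_json(
    list(drug = drug, auroc = report$auroc, ba_overall = report$ba_overall,
         n_labeled = length(result$sample_ids),
         n_combinations = nrow(result$combos)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(result)
}

# Outer fold whose test set produced each sample's prediction, per repetition.
fold_of_sample <- function(result) {
  out <- matrix(NA_integer_, length(result$sample_ids), length(result$first_level),
                dimnames = list(result$sample_ids, NULL))
  for (r in seq_along(result$first_level)) {
    fl <- result$first_level[[r]]
    if (is.null(fl$folds)) next
    for (f in seq_along(fl$folds)) out[fl$folds[[f]]$test_ids, r] <- f
  }
  out
}

# Every labeled sample's first-level test-fold probabilities (one row per
# sample, assembled from the outer fold where the sample was held out).
test_prediction_matrix <- function(result, repetition = 1) {
  fl <- result$first_level[[repetition]]
  if (is.null(fl$folds)) stop("needs keep_matrices = TRUE")
  do.call(rbind, lapply(fl$folds, `[[`, "test_mat"))[result$sample_ids, , drop = FALSE]
}
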