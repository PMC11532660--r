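test_that("every labeled sample gets one prediction per repetition, leak-free", {
  run <- small_stacked_run()
  res <- run$res
  expect_false(anyNA(res$per_repetition))
  expect_equal(ncol(res$per_repetition), 2)
  expect_true(all(res$final_probability >= 0 & res$final_probability <= 1))
  expect_true(isTRUE(audit_leakage(res)))
  # prediction columns: layers x registry
  expect_equal(nrow(res$combos), 4 * 3)  # 4 layers (incl. tissue) x 3 learners
  # combination importance: non-negative, sums to 1 for the RF integrator
  expect_true(all(res$combination_importance >= 0))
  expect_equal(sum(res$combination_importance), 1, tolerance = 1e-8)
})

test_that("the engine recovers planted signal and ignores noise layers", {
  run <- small_stacked_run()
  res <- run$res
  expect_gt(auroc(res$y, res$final_probability), 0.8)
  # signal-bearing layer's first-level columns rank well, noise columns do not
  pm <- omistack:::test_prediction_matrix(res, 1)
  cols <- res$combos
  tx <- cols$col_id[cols$layer == "transcriptomics" & cols$algorithm != "KNN"]
  noise <- cols$col_id[cols$layer == "proteomics" & cols$algorithm != "KNN"]
  a_tx <- vapply(tx, function(cc) auroc(res$y, pm[res$sample_ids, cc]), numeric(1))
  a_no <- vapply(noise, function(cc) auroc(res$y, pm[res$sample_ids, cc]), numeric(1))
  expect_gt(mean(a_tx), 0.75)
  expect_lt(mean(a_no), 0.65)
})

test_that("stacked runs are deterministic given the config seed", {
  sd <- small_dataset(seed = 3, n = 90)
  cfg <- stack_config(n_outer = 3, n_inner = 3, n_repetitions = 1, seed = 19,
                      registry = default_registry()[c("Logistic", "Tree")])
  r1 <- run_stacked_cv(sd$dataset, "DRUG1", cfg)
  r2 <- run_stacked_cv(sd$dataset, "DRUG1", cfg)
  expect_identical(r1$final_probability, r2$final_probability)
  expect_identical(r1$combination_importance, r2$combination_importance)
})

test_that("a single-combination registry yields a one-column prediction matrix", {
  sd <- small_dataset(seed = 4, n = 90)
  cfg <- stack_config(n_outer = 3, n_inner = 3, n_repetitions = 1, seed = 2,
                      registry = default_registry()["Logistic"],
                      layers = "transcriptomics")
  res <- run_stacked_cv(sd$dataset, "DRUG1", cfg)
  expect_equal(nrow(res$combos), 1)
  expect_equal(ncol(res$first_level[[1]]$folds[[1]]$train_mat), 1)
  expect_true(isTRUE(audit_leakage(res)))
})

test_that("the integrator finds a single informative column and reports importances", {
  set.seed(12)
  n <- 80
  y <- factor(rep(c("resistant", "sensitive"), each = n / 2),
              levels = c("resistant", "sensitive"))
  pm <- matrix(runif(n * 20), n, 20,
               dimnames = list(sprintf("S%02d", 1:n), sprintf("c%02d", 1:20)))
  pm[, 7] <- ifelse(y == "sensitive", 0.9, 0.1) + runif(n, -0.05, 0.05)
  rf <- train_integrator(pm, y, "random_forest", seed = 3)
  expect_identical(names(which.max(rf$importance)), "c07")
  expect_equal(sum(rf$importance), 1, tolerance = 1e-8)
  lg <- train_integrator(pm, y, "logistic", seed = 3)
  expect_identical(names(which.max(lg$importance)), "c07")
  expect_true(all(lg$importance >= 0))
  # deterministic per seed
  rf2 <- train_integrator(pm, y, "random_forest", seed = 3)
  expect_identical(rf$importance, rf2$importance)
  expect_identical(predict_integrator(rf, pm), predict_integrator(rf2, pm))
  expect_error(train_integrator(pm, factor(rep("sensitive", n),
                                           levels = c("resistant", "sensitive"))),
               "single-class")
})

test_that("restacking with the full column set reproduces the original run", {
  run <- small_stacked_run()
  re <- restack(run$res)
  expect_equal(re$final_probability, run$res$final_probability)
})

test_that("single-layer restriction keeps only that layer's columns", {
  run <- small_stacked_run()
  one <- restack(run$res, layers = "transcriptomics")
  expect_true(all(one$combos$layer == "transcriptomics"))
  expect_length(one$combination_importance, 3)
  # a noise-only layer scores near chance; the signal layer does not
  a_sig <- auroc(one$y, one$final_probability)
  noise <- restack(run$res, layers = "genomics")
  a_noise <- auroc(noise$y, noise$final_probability)
  expect_gt(a_sig, 0.75)
  expect_lt(abs(a_noise - 0.5), 0.2)
})

test_that("failed first-level fits degrade to 0.5 cells instead of aborting", {
  sd <- small_dataset(seed = 6, n = 90)
  broken <- default_registry()["Logistic"]
  # rpart rejects maxdepth > 30, so every fit of this spec errors out
  broken$Broken <- learner_spec("Tree", "single_tree", list(maxdepth = 99))
  cfg <- stack_config(n_outer = 3, n_inner = 3, n_repetitions = 1, seed = 3,
                      registry = broken, layers = "transcriptomics")
  expect_warning(res <- run_stacked_cv(sd$dataset, "DRUG1", cfg), "failed")
  bad_col <- res$combos$col_id[res$combos$algorithm == "Broken"]
  expect_true(all(res$first_level[[1]]$folds[[1]]$train_mat[, bad_col] == 0.5))
  expect_false(is.null(res$first_level[[1]]$failures))
})
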