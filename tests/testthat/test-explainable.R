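# Cohort whose entire signal lives in three transcriptomic markers:
# the distillation target regime.
distill_setup <- function(seed = 101, n = 150) {
  gd <- generate_dataset(small_config(seed = seed, n = n, markers = 3,
                                      effect = 2))
  ds <- preprocess_dataset(gd$dataset)
  res <- run_stacked_cv(ds, "DRUG1",
                        stack_config(n_outer = 5, n_inner = 5,
                                     n_repetitions = 1, seed = seed,
                                     registry = fast_registry()))
  list(dataset = ds, truth = gd$truth, res = res,
       imp = layer_importance_table(res, "transcriptomics"))
}

.distill_cache <- new.env(parent = emptyenv())
get_distill_setup <- function() {
  if (is.null(.distill_cache$s)) .distill_cache$s <- distill_setup()
  .distill_cache$s
}

test_that("distillation keeps three features and records all three candidates", {
  s <- get_distill_setup()
  dm <- distill(s$dataset, "DRUG1", s$imp,
                config = stack_config(n_outer = 5, n_inner = 5, seed = 5))
  expect_length(dm$feature_ids, 3)
  expect_setequal(names(dm$selection_record), c("linear", "logistic", "tree"))
  expect_equal(dm$auroc_cv, max(dm$selection_record))
  expect_true(dm$model_type %in% names(dm$selection_record))
  # strong planted markers: every candidate separates well
  expect_true(all(dm$selection_record > 0.8))
  # the selected features overlap the planted markers
  mk <- s$truth$marker_ids$transcriptomics
  expect_gte(length(intersect(dm$feature_ids, mk)), 2)
  # the tree candidate stays human-readable
  nodes <- as.integer(rownames(dm$model$fit$frame))
  if (dm$model_type == "tree") expect_lte(max(floor(log2(nodes))), 3)
})

test_that("distillation needs at least three surviving features", {
  s <- get_distill_setup()
  expect_error(distill(s$dataset, "DRUG1", s$imp[1:2, ]), "fewer than 3")
})

test_that("feature order in the importance table does not change the model", {
  s <- get_distill_setup()
  cfg <- stack_config(n_outer = 5, n_inner = 5, seed = 5)
  d1 <- distill(s$dataset, "DRUG1", s$imp, config = cfg)
  perm <- s$imp[sample(nrow(s$imp)), ]
  d2 <- distill(s$dataset, "DRUG1", perm, config = cfg)
  expect_identical(d1$feature_ids, d2$feature_ids)
  expect_equal(predict_distilled(d1, d1$train_X),
               predict_distilled(d2, d2$train_X))
})

test_that("partial-dependence surfaces have the geometry of their model class", {
  s <- get_distill_setup()
  cfg <- stack_config(n_outer = 5, n_inner = 5, seed = 5)
  dm <- distill(s$dataset, "DRUG1", s$imp, config = cfg)

  for (type in c("linear", "logistic", "tree")) {
    m <- dm
    m$model <- omistack:::fit_candidates(dm$train_X,
                                         m$labels$label[rownames(dm$train_X)],
                                         tree_depth = 3)[[type]]
    m$model_type <- type
    surf <- partial_dependence_2d(m, dm$feature_ids[1:2], grid_resolution = 9)
    expect_equal(dim(surf$z), c(9, 9))
    if (type == "linear") {
      # planar: second differences vanish along both axes
      expect_lt(max(abs(diff(diff(surf$z)))), 1e-8)
      expect_lt(max(abs(t(diff(diff(t(surf$z)))))), 1e-8)
    }
    if (type == "tree") {
      # piecewise constant: few unique values
      expect_lte(length(unique(round(as.vector(surf$z), 10))), 8)
    }
    if (type == "logistic") {
      sg <- sign(diff(surf$z[, 1]))
      expect_true(all(sg >= 0) || all(sg <= 0))  # monotone along an axis
    }
  }
  expect_error(partial_dependence_2d(dm, dm$feature_ids[1:2], 1), "grid_resolution")
  expect_error(partial_dependence_2d(dm, c("nope1", "nope2")), "among")
})

test_that("frozen models transfer to an external cohort carrying the same markers", {
  s <- get_distill_setup()
  cfg <- stack_config(n_outer = 5, n_inner = 5, seed = 5)
  dm <- distill(s$dataset, "DRUG1", s$imp, config = cfg)

  ext_cfg <- small_config(seed = 999, n = 150, markers = 3, effect = 2)
  ext_cfg$marker_ids <- list(transcriptomics = s$truth$marker_ids$transcriptomics)
  ext <- generate_dataset(ext_cfg)
  rep <- evaluate_transfer(dm, ext$dataset)
  expect_lt(abs(rep$auroc - dm$auroc_cv), 0.1)

  # permuted labels: transfer collapses to chance
  lab <- make_labels(preprocess_dataset(ext$dataset, variance_drop_fraction = 0,
                                        correlation_max = 1), "DRUG1")
  plab <- permute_labels(lab, seed = 4)
  ids <- labeled_ids(plab)
  pp <- preprocess_dataset(ext$dataset, variance_drop_fraction = 0,
                           correlation_max = 1)
  sc <- predict_distilled(dm, layer_matrix(pp, "transcriptomics", ids))
  null_a <- auroc(plab$label[ids] == "sensitive", sc)
  expect_lt(abs(null_a - 0.5), 0.15)

  # a cohort missing one of the three features is rejected by name
  broken <- ext$dataset
  keep <- setdiff(feature_ids(broken$layers$transcriptomics), dm$feature_ids[1])
  broken$layers$transcriptomics$values <-
    broken$layers$transcriptomics$values[, keep]
  err <- tryCatch(evaluate_transfer(dm, broken), error = conditionMessage)
  expect_match(err, dm$feature_ids[1], fixed = TRUE)
})
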