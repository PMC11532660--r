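#' Distill a stacked ensemble into a three-feature explainable model
#'
#' Takes the three best-ranked features of one layer (transcriptomics by
#' default, where most predictive signal concentrates), fits three
#' candidate models chosen for interpretability — linear regression
#' (raw predicted value used as the ranking score), logistic regression,
#' and a single depth-bounded decision tree — under the same
#' cross-validation geometry as the full pipeline, and keeps the
#' candidate with the largest out-of-fold AUROC. Note the features are
#' fixed from the prior importance analysis before this CV, mirroring
#' the top-down construction of the teacher analysis (a known optimistic
#' bias, preserved deliberately).
#'
#' AUROC ties are resolved by the documented preference order
#' logistic > tree > linear.
#'
#' @param dataset A `multiomic_dataset`.
#' @param drug Drug to model.
#' @param importance Importance table for the chosen layer
#'   ([layer_importance_table()] or [importance_table()] output).
#' @param layer Feature source layer (default `"transcriptomics"`).
#' @param config A [stack_config()]; its outer-fold geometry and seed
#'   drive the selection CV.
#' @param labels Optional precomputed `response_labels`.
#' @param tree_depth Depth bound of the tree candidate (default 3, keeps
#'   the structure human-readable).
#' @return A `distilled_model`: `feature_ids` (exactly 3), `model_type`,
#'   the fitted model, `auroc_cv`, and `selection_record` with the CV
#'   AUROC of all three candidates.
#' @export
distill <- function(dataset, drug, importance, layer = "transcriptomics",
                    config = stack_config(), labels = NULL, tree_depth = 3) {
  dataset <- preprocess_dataset(dataset)
  labels <- labels %||% make_labels(dataset, drug, scheme = config$labeling_scheme)
  ids <- intersect(dataset$sample_ids, labeled_ids(labels))
  y <- binary_labels(labels, ids)
  if (nrow(importance) < 3) stop("fewer than 3 surviving features in the importance table")
  feats <- top_features(importance, 3)$feature_id
  X <- layer_matrix(dataset, layer, samples = ids)
  missing <- setdiff(feats, colnames(X))
  if (length(missing)) stop("features absent from layer '", layer, "': ",
                            paste(missing, collapse = ", "))
  X <- X[, feats, drop = FALSE]

  set.seed(config$seed)
  plan <- make_fold_plan(ids, y, config$n_outer, config$n_inner,
                         seed = sample.int(.Machine$integer.max - 1, 1))
  oof <- matrix(NA_real_, length(ids), 3,
                dimnames = list(ids, c("linear", "logistic", "tree")))
  for (f in seq_len(plan$n_outer)) {
    o <- plan$outer[[f]]
    fits <- fit_candidates(X[o$train, , drop = FALSE], y[o$train], tree_depth)
    for (k in colnames(oof))
      oof[o$test, k] <- score_candidate(fits[[k]], X[o$test, , drop = FALSE])
  }
  record <- vapply(colnames(oof), function(k) auroc(y, oof[, k]), numeric(1))
  pref <- c("logistic", "tree", "linear")  # tie preference
  best <- pref[which.max(record[pref])]

  final <- fit_candidates(X, y, tree_depth)[[best]]
  structure(list(drug = drug, layer = layer, feature_ids = feats,
                 model_type = best, model = final,
                 auroc_cv = unname(record[best]), selection_record = record,
                 tree_depth = tree_depth, train_X = X, labels = labels,
                 scheme = labels$scheme),
            class = "distilled_model")
}

fit_candidates <- function(X, y, tree_depth) {
  y <- factor(as.character(y), levels = c("resistant", "sensitive"))
  df <- as.data.frame(X)
  safe <- make.names(colnames(X), unique = TRUE)
  colnames(df) <- safe
  dfl <- df; dfl$.y <- as.integer(y == "sensitive")
  dfc <- df; dfc$.y <- y
  list(
    linear = list(fit = stats::lm(.y ~ ., data = dfl), safe = safe, type = "linear"),
    logistic = list(fit = suppressWarnings(glm(.y ~ ., data = dfl, family = binomial())),
                    safe = safe, type = "logistic"),
    tree = list(fit = rpart::rpart(.y ~ ., data = dfc, method = "class",
                                   control = rpart::rpart.control(
                                     maxdepth = tree_depth, cp = 0.01, xval = 0)),
                safe = safe, type = "tree")
  )
}

score_candidate <- function(cand, X) {
  df <- as.data.frame(X)
  colnames(df) <- cand$safe
  switch(cand$type,
         linear = as.numeric(predict(cand$fit, newdata = df)),
         logistic = as.numeric(predict(cand$fit, newdata = df, type = "response")),
         tree = as.numeric(predict(cand$fit, newdata = df, type = "prob")[, "sensitive"]))
}

#' Score new samples with a distilled model
#'
#' @param model A `distilled_model`.
#' @param X Matrix (samples x features) containing the model's three
#'   features; extra columns are ignored, feature order is irrelevant.
#' @return Numeric ranking score (probability for logistic/tree, raw
#'   linear predictor for the linear candidate).
#' @export
predict_distilled <- function(model, X) {
  missing <- setdiff(model$feature_ids, colnames(X))
  if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
  score_candidate(model$model, X[, model$feature_ids, drop = FALSE])
}

#' @export
print.distilled_model <- function(x, ...) {
  cat(sprintf("<distilled_model> %s (%s on %s): features %s, CV AUROC %.3f\n",
              x$drug, x$model_type, x$layer,
              paste(x$feature_ids, collapse = ", "), x$auroc_cv))
  invisible(x)
}

#' 2D partial-dependence surface of a distilled model
#'
#' Grid over the observed ranges of two of the model's three features,
#' with the third held at its training median; the surface is the model
#' score at each grid point. Linear candidates give a plane, logistic a
#' monotone sigmoid surface, trees an axis-aligned piecewise-constant
#' surface.
#'
#' @param model A `distilled_model`.
#' @param feature_pair Two of the model's feature ids.
#' @param grid_resolution Grid points per axis (>= 2).
#' @return A `pdp_surface`: list with `x`, `y` (grid values), `z`
#'   (resolution x resolution score matrix) and `features`.
#' @export
partial_dependence_2d <- function(model, feature_pair = model$feature_ids[1:2],
                                  grid_resolution = 25) {
  if (grid_resolution < 2) stop("grid_resolution must be >= 2")
  if (!all(feature_pair %in% model$feature_ids))
    stop("feature_pair must be among the model's features")
  if (length(feature_pair) != 2) stop("exactly two features required")
  other <- setdiff(model$feature_ids, feature_pair)
  tx <- model$train_X
  gx <- seq(min(tx[, feature_pair[1]]), max(tx[, feature_pair[1]]),
            length.out = grid_resolution)
  gy <- seq(min(tx[, feature_pair[2]]), max(tx[, feature_pair[2]]),
            length.out = grid_resolution)
  grid <- expand.grid(gx, gy)
  X <- matrix(0, nrow(grid), 3, dimnames = list(NULL, model$feature_ids))
  X[, feature_pair[1]] <- grid[[1]]
  X[, feature_pair[2]] <- grid[[2]]
  for (o in other) X[, o] <- median(tx[, o])
  z <- matrix(predict_distilled(model, X), grid_resolution, grid_resolution)
  structure(list(x = gx, y = gy, z = z, features = feature_pair,
                 held = setNames(if (length(other)) median(tx[, other]) else numeric(0), other)),
            class = "pdp_surface")
}

#' Evaluate a frozen distilled model on an external cohort
#'
#' Applies the model without refitting: the external dataset is
#' normalized (log/\[0,1\]) but not feature-filtered, labeled under the
#' model's labeling scheme, and scored with the frozen parameters. Used
#' to assess cross-database transfer of the three-gene signature.
#'
#' @param model A `distilled_model`.
#' @param external_dataset A `multiomic_dataset` providing the model's
#'   layer (with all three features) and a response column for the drug.
#' @param drug Drug in the external response table (default: the
#'   model's drug).
#' @return An `evaluation_report` (AUROC, ROC points, balanced accuracy).
#' @export
evaluate_transfer <- function(model, external_dataset, drug = model$drug) {
  if (!isTRUE(attr(external_dataset, "preprocessed"))) {
    external_dataset <- preprocess_dataset(external_dataset,
                                           variance_drop_fraction = 0,
                                           correlation_max = 1)
  }
  if (!model$layer %in% layer_names(external_dataset))
    stop("external dataset lacks layer '", model$layer, "'")
  labels <- make_labels(external_dataset, drug, scheme = model$scheme)
  ids <- intersect(external_dataset$sample_ids, labeled_ids(labels))
  y <- binary_labels(labels, ids)
  X <- layer_matrix(external_dataset, model$layer, samples = ids)
  missing <- setdiff(model$feature_ids, colnames(X))
  if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
  scores <- predict_distilled(model, X)
  structure(list(drug = drug, auroc = auroc(y, scores),
                 roc_points = roc_points(y, scores),
                 ba_overall = tryCatch(balanced_accuracy(y, scores), error = function(e) NA_real_),
                 ba_by_tissue = NULL, n = length(ids)),
            class = "evaluation_report")
}
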