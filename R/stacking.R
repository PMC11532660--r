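#' Configuration of the stacking engine
#'
#' The default geometry is the 10-fold nested scheme (10 outer folds, 10
#' inner splits, 10 independent repetitions with distinct fold seeds,
#' final probability = mean over repetitions). The `"5x5"` preset is the
#' reduced scheme used for labeling-strategy and integrator comparisons
#' (5 outer folds, 5 inner splits, one repetition).
#'
#' @param n_outer,n_inner,n_repetitions Nested-CV geometry.
#' @param integrator `"random_forest"` (default) or `"logistic"`.
#' @param integrator_trees Trees of the second-level random forest.
#' @param labeling_scheme Passed to [make_labels()].
#' @param registry First-level registry, see [default_registry()].
#' @param layers Optional character vector restricting the engine to a
#'   subset of layers (`NULL` = all layers of the dataset).
#' @param failure_value Probability filled in when a first-level fit
#'   fails on one (layer, algorithm, fold) cell (degraded, not fatal).
#' @param keep_matrices Keep the per-fold prediction matrices in the
#'   result (needed by [restack()] and [audit_leakage()]).
#' @param preset `NULL` or `"5x5"`.
#' @param seed Master seed; every sub-seed derives from it.
#' @return A `stack_config` list.
#' @export
stack_config <- function(n_outer = 10, n_inner = 10, n_repetitions = 10,
                         integrator = c("random_forest", "logistic"),
                         integrator_trees = 500,
                         labeling_scheme = "tercile",
                         registry = default_registry(),
                         layers = NULL,
                         failure_value = 0.5,
                         keep_matrices = TRUE,
                         preset = NULL,
                         seed = 1) {
  integrator <- match.arg(integrator)
  if (!is.null(preset)) {
    if (preset == "5x5") {
      n_outer <- 5; n_inner <- 5; n_repetitions <- 1
    } else stop("unknown preset: ", preset)
  }
  list(n_outer = n_outer, n_inner = n_inner, n_repetitions = n_repetitions,
       integrator = integrator, integrator_trees = integrator_trees,
       labeling_scheme = labeling_scheme, registry = registry,
       layers = layers, failure_value = failure_value,
       keep_matrices = keep_matrices, seed = as.integer(seed))
}

# (layer, algorithm) combination table; column ids "layer:algo".
combo_table <- function(layer_names, registry) {
  data.frame(layer = rep(layer_names, each = length(registry)),
             algorithm = rep(names(registry), times = length(layer_names)),
             col_id = paste(rep(layer_names, each = length(registry)),
                            rep(names(registry), times = length(layer_names)),
                            sep = ":"),
             stringsAsFactors = FALSE)
}

#' First-level out-of-fold predictions for every (layer, algorithm)
#'
#' For every outer fold and every (layer, algorithm) combination, models
#' are fitted on each inner "A" set and predict the matching "B" set; the
#' B-set predictions accumulated over the inner splits give one
#' out-of-fold probability per training sample. A final model fitted on
#' the whole training set predicts the outer test set. Per-cell
#' provenance (which inner split produced it) is recorded so leakage can
#' be audited structurally. First-level feature importances of the A-set
#' fits (the sub-folds) are accumulated as rank sums per combination.
#'
#' @param dataset A preprocessed `multiomic_dataset`.
#' @param y Binary factor named by sample id (intermediates excluded).
#' @param plan A [make_fold_plan()] plan.
#' @param registry Learner registry.
#' @param layers Layers to use (default: all).
#' @param failure_value Fill-in probability for failed fits.
#' @param seed Seed for the per-fit seed stream.
#' @return A `first_level` object: per-fold train/test prediction
#'   matrices with provenance, importance accumulators and a failure log.
#' @export
run_first_level <- function(dataset, y, plan, registry,
                            layers = NULL, failure_value = 0.5, seed = 1) {
  layers <- layers %||% layer_names(dataset)
  combos <- combo_table(layers, registry)
  ids <- plan$sample_ids
  y <- y[ids]
  Xl <- lapply(layers, function(l) layer_matrix(dataset, l, samples = ids))
  names(Xl) <- layers

  set.seed(seed)
  fit_seeds <- array(sample.int(.Machine$integer.max - 1,
                                nrow(combos) * plan$n_outer * (plan$n_inner + 1)),
                     dim = c(nrow(combos), plan$n_outer, plan$n_inner + 1))

  p_feat <- vapply(Xl, ncol, integer(1))
  imp_acc <- lapply(seq_len(nrow(combos)), function(ci) {
    p <- p_feat[[combos$layer[ci]]]
    fid <- colnames(Xl[[combos$layer[ci]]])
    list(rank_sum = setNames(numeric(p), fid),
         imp_sum = setNames(numeric(p), fid), n = 0L)
  })
  names(imp_acc) <- combos$col_id
  failures <- list()

  folds <- vector("list", plan$n_outer)
  for (f in seq_len(plan$n_outer)) {
    o <- plan$outer[[f]]
    train_mat <- matrix(NA_real_, length(o$train), nrow(combos),
                        dimnames = list(o$train, combos$col_id))
    prov <- matrix(NA_integer_, length(o$train), nrow(combos),
                   dimnames = list(o$train, combos$col_id))
    test_mat <- matrix(NA_real_, length(o$test), nrow(combos),
                       dimnames = list(o$test, combos$col_id))
    for (ci in seq_len(nrow(combos))) {
      spec <- registry[[combos$algorithm[ci]]]
      X <- Xl[[combos$layer[ci]]]
      track <- spec$importance_mode != "none"
      for (i in seq_len(plan$n_inner)) {
        a_ids <- a_set(plan, f, i); b_ids <- o$b_sets[[i]]
        pr <- tryCatch({
          fit <- fit_learner(spec, X[a_ids, , drop = FALSE], y[a_ids],
                             seed = fit_seeds[ci, f, i])
          if (track) {
            imp <- fit$importance
            acc <- imp_acc[[ci]]
            acc$rank_sum <- acc$rank_sum + rank_features(imp)
            acc$imp_sum <- acc$imp_sum + imp
            acc$n <- acc$n + 1L
            imp_acc[[ci]] <- acc
          }
          predict_proba(fit, X[b_ids, , drop = FALSE])
        }, error = function(e) {
          failures[[length(failures) + 1]] <<-
            data.frame(fold = f, inner = i, layer = combos$layer[ci],
                       algorithm = combos$algorithm[ci],
                       message = conditionMessage(e), stringsAsFactors = FALSE)
          rep(failure_value, length(b_ids))
        })
        train_mat[b_ids, ci] <- pr
        prov[b_ids, ci] <- i
      }
      test_mat[, ci] <- tryCatch({
        fit <- fit_learner(spec, X[o$train, , drop = FALSE], y[o$train],
                           seed = fit_seeds[ci, f, plan$n_inner + 1])
        predict_proba(fit, X[o$test, , drop = FALSE])
      }, error = function(e) {
        failures[[length(failures) + 1]] <<-
          data.frame(fold = f, inner = NA_integer_, layer = combos$layer[ci],
                     algorithm = combos$algorithm[ci],
                     message = conditionMessage(e), stringsAsFactors = FALSE)
        rep(failure_value, length(o$test))
      })
    }
    folds[[f]] <- list(train_ids = o$train, test_ids = o$test,
                       train_mat = train_mat, prov = prov, test_mat = test_mat)
  }
  if (length(failures))
    warning(length(failures), " first-level fit(s) failed; cells filled with ",
            failure_value, call. = FALSE)
  structure(list(combos = combos, folds = folds, imp_acc = imp_acc,
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 plan = plan),
            class = "first_level")
}

#' Train the second-level integrator
#'
#' Fits on the out-of-fold first-level probabilities cumulated over the
#' inner splits of one outer fold. The random-forest integrator exposes
#' per-(layer, algorithm) importance as internal-node fractions (sums to
#' 1); the logistic integrator as absolute coefficients.
#'
#' @param train_matrix Samples x (layer, algorithm) probability matrix.
#' @param y Binary factor aligned with the rows.
#' @param kind `"random_forest"` or `"logistic"`.
#' @param num.trees Random-forest size.
#' @param seed Integer seed.
#' @return An `integrator` object with elements `kind`, `model`,
#'   `importance`.
#' @export
train_integrator <- function(train_matrix, y, kind = c("random_forest", "logistic"),
                             num.trees = 500, seed = 1) {
  kind <- match.arg(kind)
  y <- factor(y, levels = c("resistant", "sensitive"))
  if (any(table(y) == 0)) stop("single-class labels for integrator")
  set.seed(seed)
  if (kind == "random_forest") {
    model <- ranger::ranger(x = train_matrix, y = y, probability = TRUE,
                            num.trees = num.trees, num.threads = 1, seed = seed)
    counts <- setNames(numeric(ncol(train_matrix)), colnames(train_matrix))
    for (t in seq_len(model$num.trees)) {
      sv <- ranger::treeInfo(model, t)$splitvarName
      sv <- sv[!is.na(sv)]
      if (length(sv)) {
        tab <- table(sv)
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
    }
    importance <- if (sum(counts) > 0) counts / sum(counts) else counts
  } else {
    lam <- 1 / nrow(train_matrix)
    model <- glmnet::glmnet(train_matrix, y, family = "binomial", alpha = 0,
                            lambda = lam * c(16, 8, 4, 2, 1))
    attr(model, "lambda_use") <- lam
    importance <- abs(as.matrix(coef(model, s = lam))[-1, 1])
    names(importance) <- colnames(train_matrix)
  }
  structure(list(kind = kind, model = model, importance = importance,
                 feature_ids = colnames(train_matrix)),
            class = "integrator")
}

#' Predict sensitive-class probability from an integrator
#' @param integrator An `integrator`.
#' @param newdata Prediction matrix with the training columns.
#' @return Named probability vector.
#' @export
predict_integrator <- function(integrator, newdata) {
  newdata <- newdata[, integrator$feature_ids, drop = FALSE]
  pr <- if (integrator$kind == "random_forest") {
    predict(integrator$model, data = newdata, num.threads = 1)$predictions[, "sensitive"]
  } else {
    drop(predict(integrator$model, newdata, s = attr(integrator$model, "lambda_use"),
                 type = "response"))
  }
  setNames(as.numeric(pr), rownames(newdata))
}

#' Run the full stacked nested cross-validation for one drug
#'
#' Executes the complete two-level procedure: response labeling,
#' first-level out-of-fold probabilities per (layer, algorithm), a
#' second-level integrator per outer fold predicting that fold's test
#' samples, repeated `n_repetitions` times with distinct fold seeds. The
#' final probability of every labeled sample is the mean of its
#' test-fold predictions across repetitions, so no prediction ever comes
#' from a model that saw the sample.
#'
#' @param dataset A `multiomic_dataset`; preprocessed automatically if
#'   not already (with cascade defaults).
#' @param drug Drug name in the response table.
#' @param config A [stack_config()].
#' @param labels Optional precomputed `response_labels` (e.g. permuted
#'   labels for a null control); default labels come from
#'   [make_labels()] under the config's scheme.
#' @return A `stacked_result` with `final_probability`,
#'   `per_repetition`, `combination_importance`, importance accumulators
#'   and (when `keep_matrices`) the per-repetition first-level objects.
#' @export
run_stacked_cv <- function(dataset, drug, config = stack_config(), labels = NULL) {
  dataset <- preprocess_dataset(dataset)
  labels <- labels %||% make_labels(dataset, drug, scheme = config$labeling_scheme)
  ids <- intersect(dataset$sample_ids, labeled_ids(labels))
  y <- binary_labels(labels, ids)
  layers <- config$layers %||% layer_names(dataset)

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, config$n_repetitions * 2)

  per_rep <- matrix(NA_real_, length(ids), config$n_repetitions,
                    dimnames = list(ids, NULL))
  firsts <- vector("list", config$n_repetitions)
  comb_imp_sum <- NULL; comb_imp_n <- 0L
  imp_acc <- NULL

  for (r in seq_len(config$n_repetitions)) {
    plan <- make_fold_plan(ids, y, config$n_outer, config$n_inner,
                           seed = rep_seeds[r])
    fl <- run_first_level(dataset, y, plan, config$registry, layers = layers,
                          failure_value = config$failure_value,
                          seed = rep_seeds[config$n_repetitions + r])
    for (f in seq_along(fl$folds)) {
      fo <- fl$folds[[f]]
      integ <- train_integrator(fo$train_mat, y[fo$train_ids],
                                kind = config$integrator,
                                num.trees = config$integrator_trees,
                                seed = rep_seeds[r] + f)
      per_rep[fo$test_ids, r] <- predict_integrator(integ, fo$test_mat)
      comb_imp_sum <- if (is.null(comb_imp_sum)) integ$importance else comb_imp_sum + integ$importance
      comb_imp_n <- comb_imp_n + 1L
    }
    imp_acc <- merge_imp_acc(imp_acc, fl$imp_acc)
    firsts[[r]] <- if (config$keep_matrices) fl else fl[c("combos", "imp_acc", "failures")]
  }

  structure(list(
    drug = drug, labels = labels, y = y, sample_ids = ids,
    final_probability = rowMeans(per_rep),
    per_repetition = per_rep,
    combination_importance = comb_imp_sum / comb_imp_n,
    combos = combo_table(layers, config$registry),
    integrator_kind = config$integrator,
    imp_acc = imp_acc,
    first_level = firsts,
    config = config), class = "stacked_result")
}

merge_imp_acc <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(b)) {
    a[[k]]$rank_sum <- a[[k]]$rank_sum + b[[k]]$rank_sum
    a[[k]]$imp_sum <- a[[k]]$imp_sum + b[[k]]$imp_sum
    a[[k]]$n <- a[[k]]$n + b[[k]]$n
  }
  a
}

#' @export
print.stacked_result <- function(x, ...) {
  cat(sprintf("<stacked_result> drug %s: %d labeled samples, %d combinations, %d repetition(s), %s integrator\n",
              x$drug, length(x$sample_ids), nrow(x$combos),
              ncol(x$per_repetition), x$integrator_kind))
  cat(sprintf("  aggregate AUROC: %.3f\n", auroc(x$y, x$final_probability)))
  invisible(x)
}

#' Stacked CV restricted to a single omic layer
#'
#' Identical engine, with the second-level integrator drawing only on the
#' chosen layer's (layer, algorithm) columns.
#'
#' @inheritParams run_stacked_cv
#' @param layer Layer name.
#' @return A `stacked_result`.
#' @export
run_single_layer_cv <- function(dataset, drug, layer, config = stack_config(),
                                labels = NULL) {
  config$layers <- layer
  run_stacked_cv(dataset, drug, config, labels = labels)
}

#' Re-train the integrator of an existing run on a column subset
#'
#' The first-level out-of-fold probabilities of a `stacked_result` depend
#' only on their own (layer, algorithm) pair, so alternative integrators
#' (a single layer, a different integrator kind) can be evaluated without
#' re-fitting the first level. Requires `keep_matrices = TRUE` in the
#' original config.
#'
#' @param result A `stacked_result`.
#' @param layers Optional layer subset.
#' @param integrator Optional integrator kind override.
#' @return A new `stacked_result` (importance accumulators restricted to
#'   the kept columns).
#' @export
restack <- function(result, layers = NULL, integrator = NULL) {
  if (!length(result$first_level) || is.null(result$first_level[[1]]$folds))
    stop("restack needs keep_matrices = TRUE in the original run")
  config <- result$config
  kind <- integrator %||% result$integrator_kind
  keep <- if (is.null(layers)) result$combos$col_id else
    result$combos$col_id[result$combos$layer %in% layers]
  if (!length(keep)) stop("no columns left after layer restriction")

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, config$n_repetitions * 2)
  per_rep <- result$per_repetition; per_rep[] <- NA_real_
  comb_imp_sum <- NULL; comb_imp_n <- 0L
  for (r in seq_along(result$first_level)) {
    fl <- result$first_level[[r]]
    for (f in seq_along(fl$folds)) {
      fo <- fl$folds[[f]]
      integ <- train_integrator(fo$train_mat[, keep, drop = FALSE],
                                result$y[fo$train_ids], kind = kind,
                                num.trees = config$integrator_trees,
                                seed = rep_seeds[r] + f)
      per_rep[fo$test_ids, r] <- predict_integrator(integ, fo$test_mat[, keep, drop = FALSE])
      comb_imp_sum <- if (is.null(comb_imp_sum)) integ$importance else comb_imp_sum + integ$importance
      comb_imp_n <- comb_imp_n + 1L
    }
  }
  out <- result
  out$final_probability <- rowMeans(per_rep)
  out$per_repetition <- per_rep
  out$combination_importance <- comb_imp_sum / comb_imp_n
  out$combos <- result$combos[result$combos$col_id %in% keep, , drop = FALSE]
  out$integrator_kind <- kind
  out$imp_acc <- result$imp_acc[keep[keep %in% names(result$imp_acc)]]
  out
}

#' Structural leakage audit of a stacked run
#'
#' Asserts, cell by cell, that no out-of-fold prediction was produced by
#' a model whose training set contained the predicted sample: training
#' cells must come from the inner split whose B set holds the sample
#' (so the fitted A set excludes it), and test cells belong to samples
#' outside the outer training set. Purely structural, no statistics.
#'
#' @param result A `stacked_result` run with `keep_matrices = TRUE`.
#' @return `TRUE` (invisibly) when clean; otherwise a character vector of
#'   violations.
#' @export
audit_leakage <- function(result) {
  violations <- character(0)
  for (r in seq_along(result$first_level)) {
    fl <- result$first_level[[r]]
    if (is.null(fl$folds)) stop("audit needs keep_matrices = TRUE")
    plan <- fl$plan
    ok <- validate_fold_plan(plan)
    if (!isTRUE(ok)) violations <- c(violations, paste0("rep ", r, ": ", ok))
    for (f in seq_along(fl$folds)) {
      fo <- fl$folds[[f]]
      if (length(intersect(fo$test_ids, fo$train_ids)))
        violations <- c(violations, sprintf("rep %d fold %d: test/train overlap", r, f))
      # split whose B set holds each training sample: the only split whose
      # A set excludes it, hence the only legal producer of its cell
      b_of <- rep(NA_integer_, length(fo$train_ids))
      names(b_of) <- fo$train_ids
      for (i in seq_along(plan$outer[[f]]$b_sets))
        b_of[plan$outer[[f]]$b_sets[[i]]] <- i
      if (anyNA(fo$prov))
        violations <- c(violations, sprintf("rep %d fold %d: missing provenance", r, f))
      bad <- which(fo$prov != b_of[rownames(fo$prov)], arr.ind = TRUE)
      if (nrow(bad))
        violations <- c(violations,
                        sprintf("rep %d fold %d: %s predicted by a model trained on it",
                                r, f, rownames(fo$prov)[bad[, 1]]))
    }
  }
  if (length(violations)) violations else invisible(TRUE)
}
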