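#' Specification of a first-level learner
#'
#' Each learner obeys a uniform contract: `fit_learner()` on a numeric
#' samples x features matrix with a binary resistant/sensitive factor,
#' `predict_proba()` returning the probability of the sensitive class,
#' and a per-feature importance. Tree-based learners report importance as
#' the fraction of internal (non-leaf) nodes splitting on the feature,
#' normalized to sum to 1; regression-based learners report the absolute
#' value of the coefficients (unnormalized); k-nearest neighbors has no
#' importance (all zeros).
#'
#' @param key Short identifier, e.g. `"RFC"`.
#' @param family One of `"tree_ensemble"`, `"linear"`, `"margin"`,
#'   `"neighbors"`, `"single_tree"`.
#' @param params Named list of hyperparameters (engine-specific).
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(key, family = c("tree_ensemble", "linear", "margin",
                                         "neighbors", "single_tree"),
                         params = list()) {
  family <- match.arg(family)
  engine <- switch(key,
                   RFC = "ranger", ET = "ranger", XGB = "xgb", Ada = "ada",
                   EN = "glmnet_binomial", Logistic = "glmnet_binomial",
                   Ridge = "ridge_platt", KNN = "knn", SVM = "svm",
                   Tree = "rpart",
                   stop("unknown learner key: ", key))
  importance_mode <- switch(family,
                            tree_ensemble = "node_fraction",
                            single_tree = "node_fraction",
                            linear = "abs_coefficient",
                            margin = "abs_coefficient",
                            neighbors = "none")
  structure(list(key = key, family = family, engine = engine,
                 importance_mode = importance_mode, params = params),
            class = "learner_spec")
}

#' The default registry of 10 first-level algorithms
#'
#' Random forest (RFC), extra-trees (ET), XGBoost (XGB), AdaBoost over
#' decision stumps (Ada), elastic-net logistic regression (EN),
#' ridge-regression classifier with a calibrated logistic link (Ridge),
#' k-nearest neighbors (KNN), linear-kernel SVM (SVM), L2-penalized
#' logistic regression (Logistic), and a single decision tree (Tree).
#' With the default seven omic layers this yields 70 (layer, algorithm)
#' prediction columns for the second-level integrator.
#'
#' @param exclude Character vector of keys to drop from the registry.
#' @return Named list of [learner_spec()] objects.
#' @export
default_registry <- function(exclude = NULL) {
  reg <- list(
    RFC = learner_spec("RFC", "tree_ensemble",
                       list(num.trees = 100, splitrule = "gini")),
    ET = learner_spec("ET", "tree_ensemble",
                      list(num.trees = 100, splitrule = "extratrees")),
    XGB = learner_spec("XGB", "tree_ensemble",
                       list(nrounds = 50, max_depth = 3, eta = 0.3)),
    Ada = learner_spec("Ada", "tree_ensemble", list(n_rounds = 50)),
    EN = learner_spec("EN", "linear", list(alpha = 0.5)),
    Ridge = learner_spec("Ridge", "linear", list()),
    KNN = learner_spec("KNN", "neighbors", list(k = 5)),
    SVM = learner_spec("SVM", "margin", list(cost = 1)),
    Logistic = learner_spec("Logistic", "linear", list(alpha = 0)),
    Tree = learner_spec("Tree", "single_tree", list(maxdepth = 30))
  )
  if (!is.null(exclude)) reg <- reg[setdiff(names(reg), exclude)]
  reg
}

# Logistic (Platt) link calibrated on training decision values; maps a
# margin/regression score to a probability of the sensitive class.
platt_fit <- function(y, s) {
  yy <- as.integer(y == "sensitive")
  if (length(unique(s)) < 2) return(list(a = 0, b = qlogis(pmin(pmax(mean(yy), 1e-6), 1 - 1e-6))))
  fit <- suppressWarnings(glm(yy ~ s, family = binomial()))
  list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
}

platt_predict <- function(calib, s) plogis(calib$b + calib$a * s)

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have feature colnames")
  y <- factor(y, levels = c("resistant", "sensitive"))
  if (anyNA(y)) stop("labels must be resistant/sensitive")
  if (any(table(y) == 0)) stop("single-class labels: both classes required to fit")
  list(X = X, y = y)
}

#' Fit one first-level learner
#'
#' @param spec A [learner_spec()].
#' @param X Numeric samples x features matrix (no missing values).
#' @param y Factor with levels resistant/sensitive (both present).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @return A `fitted_learner` with the per-feature `importance` populated
#'   according to the spec's importance mode.
#' @export
fit_learner <- function(spec, X, y, seed = 1) {
  cc <- check_xy(X, y); X <- cc$X; y <- cc$y
  seed <- as.integer(seed) %% .Machine$integer.max
  set.seed(seed)
  p <- spec$params
  model <- NULL; calib <- NULL; extra <- list()

  if (spec$engine == "ranger") {
    model <- ranger::ranger(x = X, y = y, probability = TRUE,
                            num.trees = p$num.trees %||% 100,
                            splitrule = p$splitrule %||% "gini",
                            min.node.size = p$min.node.size %||% 10,
                            num.threads = 1, seed = seed)
  } else if (spec$engine == "xgb") {
    d <- xgboost::xgb.DMatrix(X, label = as.integer(y == "sensitive"), nthread = 1)
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = p$max_depth %||% 3, eta = p$eta %||% 0.3,
                    nthread = 1, seed = seed),
      data = d, nrounds = p$nrounds %||% 50, verbose = 0)
  } else if (spec$engine == "ada") {
    yy <- ifelse(y == "sensitive", 1, -1)
    model <- fit_adaboost(X, yy, n_rounds = p$n_rounds %||% 50)
    calib <- platt_fit(y, adaboost_decision(model, X))
  } else if (spec$engine == "glmnet_binomial") {
    lam <- p$lambda %||% (1 / nrow(X))
    Xg <- glmnet_pad(X)
    model <- glmnet::glmnet(Xg, y, family = "binomial",
                            alpha = p$alpha %||% 0.5,
                            lambda = lam * c(16, 8, 4, 2, 1))
    extra$lambda <- lam
  } else if (spec$engine == "ridge_platt") {
    lam <- p$lambda %||% (1 / nrow(X))
    Xg <- glmnet_pad(X)
    yy <- ifelse(y == "sensitive", 1, -1)
    model <- glmnet::glmnet(Xg, yy, family = "gaussian", alpha = 0,
                            lambda = lam * c(16, 8, 4, 2, 1))
    extra$lambda <- lam
    s <- drop(predict(model, Xg, s = lam))
    calib <- platt_fit(y, s)
  } else if (spec$engine == "knn") {
    model <- list(X = X, y = y, k = p$k %||% 5)
  } else if (spec$engine == "svm") {
    model <- e1071::svm(X, y, kernel = "linear", cost = p$cost %||% 1,
                        scale = FALSE)
    s <- drop(attr(predict(model, X, decision.values = TRUE), "decision.values"))
    calib <- platt_fit(y, s)
  } else if (spec$engine == "rpart") {
    df <- as.data.frame(X)
    safe <- make.names(colnames(X), unique = TRUE)
    colnames(df) <- safe
    df$.y <- y
    model <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = p$maxdepth %||% 30,
                            cp = p$cp %||% 0.01, xval = 0))
    extra$safe_names <- safe
  }

  fitted <- structure(list(spec = spec, model = model, calib = calib,
                           feature_ids = colnames(X), n_train = nrow(X),
                           seed = seed, extra = extra),
                      class = "fitted_learner")
  fitted$importance <- compute_importance(fitted)
  fitted
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# glmnet needs >= 2 columns; pad single-feature matrices with a zero dummy.
glmnet_pad <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `..pad` = 0)
}

#' Probability of the sensitive class
#'
#' @param fitted A `fitted_learner`.
#' @param X Matrix with exactly the training feature set (same order).
#' @return Named numeric vector in \[0, 1\].
#' @export
predict_proba <- function(fitted, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), fitted$feature_ids))
    stop("feature mismatch: prediction features differ from training features")
  eng <- fitted$spec$engine
  pr <- if (eng == "ranger") {
    predict(fitted$model, data = X, num.threads = 1)$predictions[, "sensitive"]
  } else if (eng == "xgb") {
    predict(fitted$model, xgboost::xgb.DMatrix(X, nthread = 1))
  } else if (eng == "ada") {
    platt_predict(fitted$calib, adaboost_decision(fitted$model, X))
  } else if (eng == "glmnet_binomial") {
    drop(predict(fitted$model, glmnet_pad(X), s = fitted$extra$lambda,
                 type = "response"))
  } else if (eng == "ridge_platt") {
    s <- drop(predict(fitted$model, glmnet_pad(X), s = fitted$extra$lambda))
    platt_predict(fitted$calib, s)
  } else if (eng == "knn") {
    set.seed(fitted$seed)
    m <- fitted$model
    pred <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
    win <- attr(pred, "prob")
    ifelse(pred == "sensitive", win, 1 - win)
  } else if (eng == "svm") {
    s <- drop(attr(predict(fitted$model, X, decision.values = TRUE),
                   "decision.values"))
    platt_predict(fitted$calib, s)
  } else if (eng == "rpart") {
    df <- as.data.frame(X)
    colnames(df) <- fitted$extra$safe_names
    predict(fitted$model, newdata = df, type = "prob")[, "sensitive"]
  }
  pr <- pmin(pmax(as.numeric(pr), 0), 1)
  names(pr) <- rownames(X)
  pr
}

#' Per-feature importance of a fitted learner
#'
#' Node fraction (tree learners): number of internal nodes splitting on
#' the feature across all trees divided by the total number of internal
#' nodes, so the vector sums to 1 whenever at least one internal node
#' exists. Absolute coefficients (regression learners): `|w_j|`,
#' unnormalized. KNN: all zeros.
#'
#' @param fitted A `fitted_learner`.
#' @return Named numeric vector (one entry per training feature).
#' @export
extract_importance <- function(fitted) fitted$importance

compute_importance <- function(fitted) {
  ids <- fitted$feature_ids
  out <- setNames(numeric(length(ids)), ids)
  eng <- fitted$spec$engine
  if (fitted$spec$importance_mode == "none") return(out)

  if (eng == "ranger") {
    counts <- out
    for (t in seq_len(fitted$model$num.trees)) {
      sv <- ranger::treeInfo(fitted$model, t)$splitvarName
      sv <- sv[!is.na(sv)]
      if (length(sv)) {
        tab <- table(sv)
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
    }
    if (sum(counts) > 0) out <- counts / sum(counts)
  } else if (eng == "xgb") {
    tr <- xgboost::xgb.model.dt.tree(model = fitted$model)
    sv <- tr$Feature[tr$Feature != "Leaf"]
    if (length(sv)) {
      tab <- table(sv)
      out[names(tab)] <- as.numeric(tab)
      out <- out / sum(out)
    }
  } else if (eng == "ada") {
    counts <- adaboost_node_counts(fitted$model)
    if (sum(counts) > 0) out <- counts / sum(counts)
  } else if (eng == "rpart") {
    vars <- as.character(fitted$model$frame$var)
    sv <- vars[vars != "<leaf>"]
    if (length(sv)) {
      tab <- table(sv)
      idx <- match(names(tab), fitted$extra$safe_names)
      out[ids[idx]] <- as.numeric(tab)
      out <- out / sum(out)
    }
  } else if (eng %in% c("glmnet_binomial", "ridge_platt")) {
    co <- as.matrix(coef(fitted$model, s = fitted$extra$lambda))[-1, 1]
    out[] <- abs(co[seq_along(ids)])
  } else if (eng == "svm") {
    w <- drop(t(fitted$model$coefs) %*% fitted$model$SV)
    out[names(w)] <- abs(w)
  }
  out
}
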