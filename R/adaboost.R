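# AdaBoost over decision stumps (discrete SAMME / AdaBoost.M1 for two
# classes), with a vectorized weighted-stump search: per round, signed
# sample weights are cumulated along each feature's sort order, so the
# best (feature, threshold, polarity) maximizes |S - 2*cumsum| in one
# matrix pass. O(rounds * n * p), no per-feature loop in R.

fit_adaboost <- function(X, yy, n_rounds = 50) {
  n <- nrow(X); p <- ncol(X)
  ord <- apply(X, 2, order)
  Xs <- matrix(X[ord + rep((seq_len(p) - 1L) * n, each = n)], n, p)
  valid <- Xs[-n, , drop = FALSE] < Xs[-1, , drop = FALSE]  # splittable gaps
  if (!any(valid)) stop("no splittable feature")

  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    W <- w * yy
    S <- sum(W)
    CS <- apply(matrix(W[ord], n, p), 2, cumsum)
    corr <- S - 2 * CS[-n, , drop = FALSE]  # rule: left -> -1, right -> +1
    a <- abs(corr)
    a[!valid] <- -Inf
    best <- arrayInd(which.max(a), dim(a))
    i <- best[1]; j <- best[2]
    polarity <- if (corr[i, j] >= 0) 1 else -1
    thr <- (Xs[i, j] + Xs[i + 1, j]) / 2
    err <- (1 - a[i, j]) / 2
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- polarity * ((X[, j] > thr) * 2 - 1)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    used <- used + 1L
    stumps[[m]] <- list(feature = j, threshold = thr,
                        polarity = polarity, alpha = alpha)
    if (err <= 1e-9) break  # perfect stump: further rounds are redundant
  }
  structure(list(stumps = stumps[seq_len(used)], feature_ids = colnames(X),
                 p = p), class = "adaboost_stumps")
}

# Additive decision value F(x) = sum_m alpha_m h_m(x).
adaboost_decision <- function(fit, X) {
  f <- numeric(nrow(X))
  for (s in fit$stumps) {
    f <- f + s$alpha * s$polarity * ((X[, s$feature] > s$threshold) * 2 - 1)
  }
  f
}

# Stump usage counts per feature (each stump has one internal node).
adaboost_node_counts <- function(fit) {
  counts <- numeric(fit$p)
  for (s in fit$stumps) counts[s$feature] <- counts[s$feature] + 1
  names(counts) <- fit$feature_ids
  counts
}
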