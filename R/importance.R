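#' Rank features by importance
#'
#' Descending importance maps to ascending rank: the most important
#' feature gets rank 1. Ties receive the mean of the tied rank positions
#' (so an all-zero importance vector, e.g. from KNN, ranks every feature
#' at `(n + 1) / 2` and each fold's ranks always sum to `n(n+1)/2`).
#'
#' @param importance Non-negative numeric vector (named or not).
#' @return Rank vector of the same length and names.
#' @export
rank_features <- function(importance) {
  if (any(importance < 0)) stop("importance must be non-negative")
  rank(-importance, ties.method = "average")
}

#' Average feature ranks across sub-folds
#'
#' Arithmetic mean of per-fold importance ranks; under the default 10
#' outer x 10 inner geometry each (layer, algorithm) pair contributes 100
#' sub-fold fits.
#'
#' @param fold_importances List of per-fold importance vectors over an
#'   identical feature set.
#' @return Named numeric vector of average ranks (lower = more important).
#' @export
average_ranks <- function(fold_importances) {
  stopifnot(length(fold_importances) > 0)
  ids <- names(fold_importances[[1]])
  for (v in fold_importances) {
    if (!identical(names(v), ids)) stop("feature sets differ across folds")
  }
  rs <- Reduce(`+`, lapply(fold_importances, rank_features))
  rs / length(fold_importances)
}

#' Per-(layer, algorithm) importance table of a stacked run
#'
#' Average rank (and mean raw importance) of every feature of one layer
#' under one algorithm, across all sub-fold fits of the run.
#'
#' @param result A `stacked_result`.
#' @param layer Layer name.
#' @param algorithm Algorithm key (e.g. `"RFC"`).
#' @return `data.frame` with columns `feature_id`, `average_rank`,
#'   `mean_importance`, sorted by ascending average rank.
#' @export
importance_table <- function(result, layer, algorithm) {
  key <- paste(layer, algorithm, sep = ":")
  acc <- result$imp_acc[[key]]
  if (is.null(acc)) stop("no importance accumulator for ", key)
  if (acc$n == 0) stop("no sub-fold fits recorded for ", key)
  out <- data.frame(feature_id = names(acc$rank_sum),
                    average_rank = acc$rank_sum / acc$n,
                    mean_importance = acc$imp_sum / acc$n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$average_rank, out$feature_id), , drop = FALSE]
}

#' Consensus importance table of one layer
#'
#' Per-algorithm average ranks are combined across the algorithms that
#' expose an importance (KNN contributes none). The default consensus is
#' the median of the per-algorithm average ranks, which highlights
#' features consistently ranked low by several algorithms and is robust
#' to a single algorithm that leaves most features unused (a lone
#' decision tree ties all unused features at a large rank).
#'
#' @param result A `stacked_result`.
#' @param layer Layer name.
#' @param stat `"median"` (default) or `"mean"` across algorithms.
#' @return `data.frame` with `feature_id`, `average_rank` (consensus),
#'   sorted ascending.
#' @export
layer_importance_table <- function(result, layer, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  algos <- unique(result$combos$algorithm[result$combos$layer == layer])
  keys <- paste(layer, algos, sep = ":")
  keys <- keys[vapply(keys, function(k) {
    !is.null(result$imp_acc[[k]]) && result$imp_acc[[k]]$n > 0 &&
      sum(result$imp_acc[[k]]$imp_sum) > 0
  }, logical(1))]
  if (!length(keys)) stop("no algorithm with importance for layer ", layer)
  per_algo <- vapply(keys, function(k) {
    acc <- result$imp_acc[[k]]
    acc$rank_sum / acc$n
  }, numeric(length(result$imp_acc[[keys[1]]]$rank_sum)))
  cons <- apply(per_algo, 1, if (stat == "median") median else mean)
  out <- data.frame(feature_id = rownames(per_algo), average_rank = cons,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$average_rank, out$feature_id), , drop = FALSE]
}

#' Top-k features by average rank
#'
#' @param table An importance table with `feature_id` and `average_rank`.
#' @param k How many features (ties broken by feature id).
#' @return `data.frame` of the `k` best-ranked features.
#' @export
top_features <- function(table, k) {
  if (k > nrow(table)) stop("k exceeds the number of features")
  if (k == 0) return(table[0, , drop = FALSE])
  table[order(table$average_rank, table$feature_id)[seq_len(k)], , drop = FALSE]
}

#' Drugs x (layer, algorithm) combination-importance matrix
#'
#' Rows are drugs, columns the (layer, algorithm) combinations, values
#' the mean second-level importance across the outer folds of each run.
#' Rows and columns are clustered with UPGMA (average linkage) on
#' Euclidean distance, as in the usual importance clustergram.
#'
#' @param results Named list (by drug) of `stacked_result` objects with
#'   identical combination sets; at least two.
#' @return A `combination_matrix`: list with `matrix`, `row_hclust`,
#'   `col_hclust`.
#' @export
build_combination_matrix <- function(results) {
  if (length(results) < 2) stop("at least two drugs required")
  if (is.null(names(results)))
    names(results) <- vapply(results, `[[`, character(1), "drug")
  cols <- names(results[[1]]$combination_importance)
  for (r in results) {
    if (!identical(names(r$combination_importance), cols))
      stop("inconsistent combination sets across drugs")
  }
  m <- do.call(rbind, lapply(results, `[[`, "combination_importance"))
  rownames(m) <- names(results)
  structure(list(matrix = m,
                 row_hclust = hclust(dist(m), method = "average"),
                 col_hclust = hclust(dist(t(m)), method = "average")),
            class = "combination_matrix")
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("<combination_matrix> %d drugs x %d combinations (UPGMA/Euclidean)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Serialize a clustergram dendrogram as Newick
#'
#' @param cm A `combination_matrix`.
#' @param which `"rows"` (drugs) or `"columns"` (combinations).
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(cm, which = c("rows", "columns"), path = NULL) {
  which <- match.arg(which)
  hc <- if (which == "rows") cm$row_hclust else cm$col_hclust
  phy <- ape::as.phylo(hc)
  # Newick reserves : ; , ( ) — replace with "_" in tip labels
  phy$tip.label <- gsub("[:;,()[:space:]]", "_", phy$tip.label)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Heatmap of the combination matrix
#'
#' Convenience clustergram rendering via pheatmap, reusing the UPGMA
#' trees computed by [build_combination_matrix()].
#'
#' @param cm A `combination_matrix`.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_combination_matrix <- function(cm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for plotting")
  p <- pheatmap::pheatmap(cm$matrix, cluster_rows = cm$row_hclust,
                          cluster_cols = cm$col_hclust, ...)
  invisible(p)
}
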