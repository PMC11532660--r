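#' Log-transform and min-max normalize a continuous layer
#'
#' Per feature: `v' = (log(v + pseudocount) - min) / (max - min)` so that
#' every non-constant feature spans exactly \[0, 1\]. Constant features map
#' to 0. Log base 10 with pseudo-count 1 keeps RPKM-like zeros at zero.
#' Boolean and categorical layers pass through unchanged.
#'
#' @param layer An [omic_layer()]. Continuous values must be non-negative.
#' @param base Logarithm base (default 10).
#' @param pseudocount Added before the log (default 1).
#' @return The transformed layer, stamped `normalized` so the operation is
#'   not applied twice.
#' @export
log_normalize <- function(layer, base = 10, pseudocount = 1) {
  minmax_step(log_step(layer, base = base, pseudocount = pseudocount))
}

# Log transform only (no scaling): the cascade ranks feature variances on
# this scale, where biological spread is still visible, before min-max
# scaling flattens it.
log_step <- function(layer, base = 10, pseudocount = 1) {
  if (layer$modality != "continuous") return(layer)
  if (isTRUE(attr(layer, "normalized")) || isTRUE(attr(layer, "logged"))) return(layer)
  v <- layer$values
  if (any(v < 0, na.rm = TRUE)) stop("layer '", layer$name, "': negative values cannot be log-transformed")
  layer$values <- log(v + pseudocount, base = base)
  attr(layer, "logged") <- TRUE
  layer
}

# Per-feature min-max scaling to [0, 1]; constant features map to 0.
minmax_step <- function(layer) {
  if (layer$modality != "continuous") return(layer)
  if (isTRUE(attr(layer, "normalized"))) return(layer)
  lv <- layer$values
  lo <- apply(lv, 2, min, na.rm = TRUE)
  hi <- apply(lv, 2, max, na.rm = TRUE)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant features -> 0 after centering
  layer$values <- sweep(sweep(lv, 2, lo, "-"), 2, rng, "/")
  attr(layer, "normalized") <- TRUE
  layer
}

#' Remove missing data without imputation
#'
#' Greedy two-step removal, applied to every layer: first drop features
#' missing in more than `f_max` of samples, then drop any sample with a
#' remaining missing value in any layer. Sample alignment across layers is
#' re-established (intersection of retained sample ids), so the result has
#' zero missing entries.
#'
#' @param dataset A `multiomic_dataset`.
#' @param f_max Maximum tolerated per-feature missingness fraction before
#'   the feature is dropped (default 0: any missing value drops the
#'   feature first, samples only remove what is left).
#' @return The dataset without missing values.
#' @export
drop_missing <- function(dataset, f_max = 0) {
  dataset$layers <- lapply(dataset$layers, function(l) {
    frac <- colMeans(is.na(l$values))
    l$values <- l$values[, frac <= f_max, drop = FALSE]
    l
  })
  bad <- Reduce(`|`, lapply(dataset$layers, function(l) rowSums(is.na(l$values)) > 0))
  keep <- dataset$sample_ids[!bad]
  subset_samples(dataset, keep)
}

#' Drop the lowest-variance fraction of features
#'
#' Features are ranked by variance across samples (ties broken by feature
#' id, so the result is deterministic) and the lowest `drop_fraction` are
#' removed; zero-variance features always rank first for removal.
#'
#' @param layer An [omic_layer()].
#' @param drop_fraction Fraction in \[0, 1) of features to remove.
#' @return The filtered layer, original column order preserved.
#' @export
variance_filter <- function(layer, drop_fraction = 0.5) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  if (drop_fraction == 0) return(layer)
  v <- apply(layer$values, 2, var)
  n_drop <- floor(ncol(layer$values) * drop_fraction)
  if (n_drop == 0) return(layer)
  ord <- order(v, colnames(layer$values))  # ascending variance, id tie-break
  drop <- colnames(layer$values)[ord[seq_len(n_drop)]]
  layer$values <- layer$values[, setdiff(colnames(layer$values), drop), drop = FALSE]
  layer
}

#' Remove highly cross-correlated features
#'
#' Greedy pass over features in descending-variance order (ties by feature
#' id): a feature is dropped when its absolute Pearson correlation with any
#' already-kept feature exceeds `r_max`. Deterministic; the higher-variance
#' member of a correlated pair survives.
#'
#' @param layer An [omic_layer()].
#' @param r_max Correlation threshold in (0, 1].
#' @return The filtered layer, original column order preserved.
#' @export
correlation_filter <- function(layer, r_max = 0.95) {
  if (r_max <= 0 || r_max > 1) stop("r_max must be in (0, 1]")
  p <- ncol(layer$values)
  if (p < 2) return(layer)
  v <- apply(layer$values, 2, var)
  ord <- order(-v, colnames(layer$values))
  cm <- suppressWarnings(abs(cor(layer$values)))
  cm[is.na(cm)] <- 0  # zero-variance features correlate with nothing
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0 || all(cm[j, kept] <= r_max)) kept <- c(kept, j)
  }
  layer$values <- layer$values[, sort(kept), drop = FALSE]
  layer
}

#' Tissue of origin from CCLE-style sample names
#'
#' Sample names follow the `CELLNAME_TISSUE` convention; the tissue is the
#' full remainder after the first underscore, which preserves multi-token
#' tissues such as `LARGE_INTESTINE`.
#'
#' @param ids Character vector of sample names, e.g. `"MCF7_BREAST"`.
#' @return Named character vector of tissues.
#' @export
extract_tissue <- function(ids) {
  bad <- !grepl("_", ids)
  if (any(bad))
    stop("sample names without a tissue suffix: ",
         paste(head(ids[bad]), collapse = ", "))
  setNames(sub("^[^_]*_", "", ids), ids)
}

#' Quantize ActArea into sensitive / intermediate / resistant
#'
#' Under the default tercile scheme, the third of cell lines with the
#' smallest ActArea is labeled resistant, the third with the largest is
#' labeled sensitive and the middle third is intermediate (and excluded
#' from all model fitting). The `quartile` scheme labels only the outer
#' quartiles; `p95` labels the outer 47.5% tails each, leaving 5%
#' unlabeled. Boundary ties are broken by sample id order.
#'
#' @param response Long response table (`sample_id`, `drug`, `act_area`) or
#'   a `multiomic_dataset`.
#' @param drug Drug name to label.
#' @param scheme `"tercile"` (default), `"quartile"` or `"p95"`.
#' @return An object of class `response_labels`: list with `drug`,
#'   `scheme` and `label`, a factor (`resistant` < `intermediate` <
#'   `sensitive`) named by sample id.
#' @export
make_labels <- function(response, drug, scheme = c("tercile", "quartile", "p95")) {
  scheme <- match.arg(scheme)
  if (inherits(response, "multiomic_dataset")) response <- response$response
  r <- response[response$drug == drug & !is.na(response$act_area), , drop = FALSE]
  if (nrow(r) < 3) stop("fewer than 3 ActArea values for drug ", drug)
  if (length(unique(r$act_area)) == 1)
    stop("all ActArea values identical for drug ", drug, ": no ordering possible")
  ord <- order(r$act_area, r$sample_id)
  n <- nrow(r)
  frac <- switch(scheme, tercile = 1 / 3, quartile = 1 / 4, p95 = 0.475)
  k <- floor(n * frac)
  lab <- rep("intermediate", n)
  lab[ord[seq_len(k)]] <- "resistant"
  lab[ord[seq.int(n - k + 1, n)]] <- "sensitive"
  structure(list(
    drug = drug, scheme = scheme,
    label = setNames(factor(lab, levels = c("resistant", "intermediate", "sensitive")),
                     r$sample_id)
  ), class = "response_labels")
}

#' Permute labels among the labeled samples (null control)
#'
#' Shuffles the sensitive/resistant assignment across the labeled
#' samples, keeping class counts and the intermediate set fixed. Breaks
#' any feature-label association, so downstream AUROC has expectation
#' 0.5 — the standard negative control for the pipeline.
#'
#' @param labels A `response_labels` object.
#' @param seed Integer seed.
#' @return A `response_labels` object with permuted assignments.
#' @export
permute_labels <- function(labels, seed = 1) {
  set.seed(seed)
  idx <- which(labels$label != "intermediate")
  labels$label[idx] <- sample(labels$label[idx])
  labels
}

#' Sample ids with a non-intermediate label
#' @param labels A `response_labels` object.
#' @return Character vector of labeled (sensitive or resistant) sample ids.
#' @export
labeled_ids <- function(labels) {
  names(labels$label)[labels$label != "intermediate"]
}

# Binary factor (resistant/sensitive) restricted to labeled samples.
binary_labels <- function(labels, ids = NULL) {
  l <- labels$label[labels$label != "intermediate"]
  l <- droplevels(l)
  if (!is.null(ids)) l <- l[ids]
  factor(l, levels = c("resistant", "sensitive"))
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: log transform of continuous layers, missing-data
#' removal (no imputation), the low-variance filter and the
#' cross-correlation filter (both ranked on the log scale, before min-max
#' scaling erases per-feature spread), then per-feature \[0,1\]
#' normalization, re-checking sample alignment throughout.
#' Layers with fewer than `variance_min_features` features (the 11-feature
#' pathway-activity layer, one-hot tissue) and categorical layers skip the
#' two filters. The dataset is stamped `preprocessed`, making the cascade
#' idempotent: a second call returns its input unchanged.
#'
#' @param dataset A `multiomic_dataset`.
#' @param log_base,pseudocount Passed to [log_normalize()].
#' @param f_max Passed to [drop_missing()].
#' @param variance_drop_fraction Passed to [variance_filter()].
#' @param correlation_max Passed to [correlation_filter()].
#' @param variance_min_features Layers below this size are exempt from the
#'   variance and correlation filters (default 20).
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(dataset, log_base = 10, pseudocount = 1,
                               f_max = 0, variance_drop_fraction = 0.5,
                               correlation_max = 0.95,
                               variance_min_features = 20) {
  if (isTRUE(attr(dataset, "preprocessed"))) return(dataset)
  dataset$layers <- lapply(dataset$layers, log_step,
                           base = log_base, pseudocount = pseudocount)
  dataset <- drop_missing(dataset, f_max = f_max)
  # variance/correlation filters see the log scale, where biological
  # spread still separates features; min-max scaling comes after
  dataset$layers <- lapply(dataset$layers, function(l) {
    if (l$modality == "categorical" || ncol(l$values) < variance_min_features) return(l)
    l <- variance_filter(l, variance_drop_fraction)
    correlation_filter(l, correlation_max)
  })
  dataset$layers <- lapply(dataset$layers, minmax_step)
  attr(dataset, "preprocessed") <- TRUE
  dataset
}
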