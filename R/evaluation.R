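#' Empirical ROC curve
#'
#' Points of the receiver-operating-characteristic curve over the unique
#' score thresholds, from (0, 0) to (1, 1), tied scores grouped (so the
#' curve is monotone non-decreasing in both coordinates and the trapezoid
#' under it equals the tie-corrected Mann-Whitney statistic).
#'
#' @param labels Binary factor (resistant/sensitive) or 0/1 vector;
#'   "sensitive"/1 is the positive class.
#' @param scores Numeric scores, larger = more sensitive.
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  pos <- as_positive(labels)
  if (all(pos) || all(!pos)) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

as_positive <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels == "sensitive"
  } else {
    labels == 1
  }
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC of [roc_points()]. With ties
#' contributing 1/2 this equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`: the probability that a random sensitive sample scores
#' above a random resistant one.
#'
#' @inheritParams roc_points
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  rp <- roc_points(labels, scores)
  sum(diff(rp$fpr) * (head(rp$tpr, -1) + rp$tpr[-1]) / 2)
}

#' Balanced accuracy
#'
#' Mean of sensitivity (true-positive rate on sensitive samples) and
#' specificity (true-negative rate on resistant samples); robust to the
#' class imbalance introduced by subsetting to one tissue.
#'
#' @param labels Binary truth (factor resistant/sensitive or 0/1).
#' @param predicted Predicted classes, or probabilities (thresholded at
#'   `threshold`).
#' @param threshold Classification threshold on probabilities.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(labels, predicted, threshold = 0.5) {
  pos <- as_positive(labels)
  if (all(pos) || all(!pos)) stop("both classes required in labels")
  pred_pos <- if (is.numeric(predicted) && !all(predicted %in% c(0, 1))) {
    predicted >= threshold
  } else {
    as_positive(predicted)
  }
  tpr <- mean(pred_pos[pos])
  tnr <- mean(!pred_pos[!pos])
  (tpr + tnr) / 2
}

#' Balanced accuracy per tissue, with small-group masking
#'
#' BA is computed on each tissue's labeled samples only and masked (set
#' to `NA`, `masked = TRUE`) when the tissue has fewer than `min_n`
#' labeled cell lines, or only one class; the sensitive/resistant counts
#' are always reported alongside.
#'
#' @param labels Binary truth, named by sample id.
#' @param predicted Probabilities or classes, aligned with `labels`.
#' @param tissue Tissue of origin per sample, aligned with `labels`.
#' @param min_n Minimum group size to report (default 10).
#' @param threshold Classification threshold on probabilities.
#' @return `data.frame`: `tissue`, `n_sensitive`, `n_resistant`, `ba`,
#'   `masked`.
#' @export
ba_by_tissue <- function(labels, predicted, tissue, min_n = 10, threshold = 0.5) {
  stopifnot(length(labels) == length(predicted), length(labels) == length(tissue))
  pos <- as_positive(labels)
  out <- lapply(sort(unique(tissue)), function(tt) {
    idx <- tissue == tt
    ns <- sum(pos[idx]); nr <- sum(!pos[idx])
    maskable <- (ns + nr) < min_n || ns == 0 || nr == 0
    ba <- if (maskable) NA_real_ else
      balanced_accuracy(labels[idx], predicted[idx], threshold = threshold)
    data.frame(tissue = tt, n_sensitive = ns, n_resistant = nr,
               ba = ba, masked = maskable, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full evaluation report for one drug's predictions
#'
#' @param result A `stacked_result` (or any list with `y`,
#'   `final_probability`, `sample_ids`).
#' @param tissue Optional tissue vector named by sample id; enables the
#'   per-tissue BA table.
#' @param min_n Masking threshold for [ba_by_tissue()].
#' @param threshold Classification threshold.
#' @return An `evaluation_report`: list with `drug`, `auroc`,
#'   `roc_points`, `ba_overall`, `ba_by_tissue`.
#' @export
evaluation_report <- function(result, tissue = NULL, min_n = 10, threshold = 0.5) {
  y <- result$y; pr <- result$final_probability
  rep <- list(drug = result$drug,
              auroc = auroc(y, pr),
              roc_points = roc_points(y, pr),
              ba_overall = balanced_accuracy(y, pr, threshold = threshold),
              ba_by_tissue = NULL)
  if (!is.null(tissue)) {
    tissue <- tissue[result$sample_ids]
    rep$ba_by_tissue <- ba_by_tissue(y, pr, tissue, min_n = min_n,
                                     threshold = threshold)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: AUROC %.3f, BA %.3f\n",
              x$drug %||% "?", x$auroc, x$ba_overall))
  invisible(x)
}

#' Long-format comparison of model configurations
#'
#' Collects AUROCs of the full stacked model, every single-layer model
#' and (optionally) the distilled explainable model into the long table
#' used for violin-style comparisons across drugs.
#'
#' @param reports Named list: configuration name -> `evaluation_report`
#'   (or anything with `auroc` and `drug`).
#' @return `data.frame` with columns `drug`, `configuration`, `auroc`.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stop("at least two configurations required")
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(drug = r$drug %||% NA_character_, configuration = nm,
               auroc = r$auroc, stringsAsFactors = FALSE)
  }))
}
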