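#' Build the nested cross-validation fold plan
#'
#' Two-level split bookkeeping: the labeled cohort is partitioned into
#' `n_outer` disjoint test sets (~10% of samples each under the default
#' 10-fold geometry). Within each outer fold, the remaining training set
#' (~90%) is partitioned into `n_inner` disjoint "B" sets (~9% of all
#' samples); the complement of a B set within the training set is the
#' corresponding "A" set (~81%) on which first-level models are fitted.
#' Both levels are stratified by class so that every split keeps both
#' classes represented; the plan is deterministic given the seed.
#'
#' @param sample_ids Character vector of labeled sample ids.
#' @param y Binary factor (resistant/sensitive) named by or aligned with
#'   `sample_ids`.
#' @param n_outer,n_inner Number of outer folds and inner splits.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `sample_ids`, `n_outer`, `n_inner`,
#'   `seed` and `outer`, a list of `(test, b_sets)` per outer fold.
#' @export
make_fold_plan <- function(sample_ids, y, n_outer = 10, n_inner = 10, seed = 1) {
  stopifnot(length(sample_ids) == length(y))
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes required to stratify folds")
  n <- length(sample_ids)
  cls_n <- table(droplevels(y))
  if (n < 20 || min(cls_n) < n_outer)
    stop("too few samples per class (", min(cls_n), ") to stratify ",
         n_outer, "-fold cross-validation")
  if (min(cls_n) - ceiling(min(cls_n) / n_outer) < n_inner)
    stop("too few samples per class to stratify ", n_inner, " inner splits")

  set.seed(seed)
  # stratified assignment that also balances total fold sizes: each class
  # is dealt in cycles over the folds, starting from the least-filled
  # folds, so e.g. 45+45 training samples give ten B sets of 9, not 10/8
  assign_strat <- function(ids, k) {
    out <- rep(NA_integer_, length(ids))
    names(out) <- ids
    counts <- integer(k)
    for (cl in levels(droplevels(y[match(ids, sample_ids)]))) {
      idx <- ids[y[match(ids, sample_ids)] == cl]
      idx <- sample(idx)
      fold_order <- order(counts, seq_len(k))
      f <- rep(fold_order, length.out = length(idx))
      out[idx] <- f
      counts <- counts + tabulate(f, nbins = k)
    }
    out
  }
  outer_assign <- assign_strat(sample_ids, n_outer)
  outer <- lapply(seq_len(n_outer), function(f) {
    test <- sample_ids[outer_assign[sample_ids] == f]
    train <- setdiff(sample_ids, test)
    inner_assign <- assign_strat(train, n_inner)
    b_sets <- lapply(seq_len(n_inner), function(i) train[inner_assign[train] == i])
    list(test = test, train = train, b_sets = b_sets)
  })
  structure(list(sample_ids = sample_ids, n_outer = n_outer,
                 n_inner = n_inner, seed = as.integer(seed), outer = outer),
            class = "fold_plan")
}

#' Training "A" set of one inner split
#' @param plan A `fold_plan`.
#' @param fold Outer fold index.
#' @param split Inner split index.
#' @return Character vector of sample ids (training set minus the B set).
#' @export
a_set <- function(plan, fold, split) {
  setdiff(plan$outer[[fold]]$train, plan$outer[[fold]]$b_sets[[split]])
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d samples, %d outer folds x %d inner splits (seed %d)\n",
              length(x$sample_ids), x$n_outer, x$n_inner, x$seed))
  invisible(x)
}

# Structural sanity of a plan: outer tests partition the cohort, B sets
# partition each training set, A and B never overlap.
validate_fold_plan <- function(plan) {
  tests <- unlist(lapply(plan$outer, `[[`, "test"))
  if (anyDuplicated(tests) || !setequal(tests, plan$sample_ids))
    return("outer test sets do not partition the cohort")
  for (f in seq_along(plan$outer)) {
    o <- plan$outer[[f]]
    bs <- unlist(o$b_sets)
    if (anyDuplicated(bs) || !setequal(bs, o$train))
      return(sprintf("inner B sets do not partition training set of fold %d", f))
    for (i in seq_along(o$b_sets)) {
      if (length(intersect(a_set(plan, f, i), o$b_sets[[i]])))
        return(sprintf("A/B overlap in fold %d split %d", f, i))
    }
  }
  TRUE
}
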