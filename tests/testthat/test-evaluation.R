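test_that("AUROC matches hand-worked cases", {
  y <- factor(c("sensitive", "sensitive", "resistant", "resistant"),
              levels = c("resistant", "sensitive"))
  # 3 of the 4 positive-negative pairs concordant
  expect_equal(auroc(y, c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auroc(y, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(y, rep(0.5, 4)), 0.5)  # all tied: 1/2 per pair
  expect_error(auroc(factor(rep("sensitive", 4),
                            levels = c("resistant", "sensitive")),
                     runif(4)), "both classes")
})

test_that("trapezoidal AUROC equals brute-force pair counting (with ties)", {
  brute <- function(pos, scores) {
    ps <- scores[pos]; ns <- scores[!pos]
    tot <- 0
    for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(ps) * length(ns))
  }
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || all(!pos)) pos[1:2] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    y <- factor(ifelse(pos, "sensitive", "resistant"),
                levels = c("resistant", "sensitive"))
    expect_equal(auroc(y, scores), brute(pos, scores), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    y <- factor(sample(c("resistant", "sensitive"), 40, replace = TRUE),
                levels = c("resistant", "sensitive"))
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          levels = c("resistant", "sensitive"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auroc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("AUROC invariances hold", {
  set.seed(29)
  y <- factor(sample(c("resistant", "sensitive"), 30, replace = TRUE),
              levels = c("resistant", "sensitive"))
  s <- runif(30)
  expect_equal(auroc(y, s), auroc(y, exp(3 * s)))     # monotone transform
  expect_equal(auroc(y, s) + auroc(y, -s), 1)         # reversal
  rp <- roc_points(y, s)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
  expect_equal(unlist(rp[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(rp[nrow(rp), c("fpr", "tpr")], use.names = FALSE), c(1, 1))
})

test_that("balanced accuracy averages sensitivity and specificity", {
  # perfect predictions on a 13-sensitive / 1-resistant group
  y <- factor(c(rep("sensitive", 13), "resistant"),
              levels = c("resistant", "sensitive"))
  expect_equal(balanced_accuracy(y, y), 1)
  # all-sensitive predictor on a mixed set: TPR 1, TNR 0
  y2 <- factor(rep(c("sensitive", "resistant"), c(30, 10)),
               levels = c("resistant", "sensitive"))
  expect_equal(balanced_accuracy(y2, rep(1, 40)), 0.5)
  # TPR 0.9, TNR 0.8 -> 0.85, and prevalence-invariant
  pred <- c(rep(c(1, 0), c(27, 3)), rep(c(0, 1), c(8, 2)))
  expect_equal(balanced_accuracy(y2, pred), 0.85)
  y3 <- factor(rep(c("sensitive", "resistant"), c(10, 30)),
               levels = c("resistant", "sensitive"))
  pred3 <- c(rep(c(1, 0), c(9, 1)), rep(c(0, 1), c(24, 6)))
  expect_equal(balanced_accuracy(y3, pred3), 0.85)
})

test_that("per-tissue BA masks groups below ten cell lines", {
  y <- factor(rep(c("sensitive", "resistant"), 14),
              levels = c("resistant", "sensitive"))
  tissue <- rep(c("LUNG", "BREAST", "SKIN"), c(10, 9, 9))
  pr <- ifelse(y == "sensitive", 0.9, 0.1)
  tab <- ba_by_tissue(y, pr, tissue)
  expect_true(tab$masked[tab$tissue == "BREAST"])
  expect_true(tab$masked[tab$tissue == "SKIN"])
  expect_false(tab$masked[tab$tissue == "LUNG"])
  expect_equal(tab$ba[tab$tissue == "LUNG"], 1)
  expect_true(is.na(tab$ba[tab$tissue == "BREAST"]))
  expect_equal(tab$n_sensitive + tab$n_resistant, c(9, 10, 9))
})

test_that("the skewed synthetic tissue mix yields both masked and reported groups", {
  run <- small_stacked_run()
  rep <- evaluation_report(run$res, tissue = run$dataset$tissue)
  expect_true(any(rep$ba_by_tissue$masked))
  expect_true(any(!rep$ba_by_tissue$masked))
  expect_gte(rep$auroc, 0); expect_lte(rep$auroc, 1)
})

test_that("model comparisons assemble into a long table", {
  mk <- function(drug, cfg, a) list(drug = drug, auroc = a)
  reports <- c(setNames(lapply(1:7, function(i) mk("D1", i, 0.6)),
                        paste0("layer", 1:7)),
               list(full = mk("D1", 8, 0.8), explainable = mk("D1", 9, 0.75)))
  tab <- compare_models(reports)
  expect_equal(nrow(tab), 9)
  expect_setequal(tab$configuration, c(paste0("layer", 1:7), "full", "explainable"))
  expect_error(compare_models(reports["full"]), "two configurations")
})
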