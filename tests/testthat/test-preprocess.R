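mklayer <- function(m, modality = "continuous", name = "x") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d_T", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  omic_layer(name, m, modality = modality)
}

test_that("log/[0,1] normalization matches the hand-computed example", {
  # log10 with pseudo-count 1: (0, 9, 99) -> (0, 1, 2) -> (0, 0.5, 1)
  l <- mklayer(cbind(a = c(0, 9, 99), b = c(5, 5, 5)))
  out <- log_normalize(l)
  expect_equal(unname(out$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$values[, "b"]), c(0, 0, 0))  # constant -> 0
  expect_error(log_normalize(mklayer(cbind(a = c(-1, 2, 3)))), "negative")

  set.seed(1)
  l2 <- log_normalize(mklayer(matrix(rexp(60), 10, 6)))
  expect_equal(unname(apply(l2$values, 2, min)), rep(0, 6))
  expect_equal(unname(apply(l2$values, 2, max)), rep(1, 6))
})

test_that("missing-data removal drops features first, then samples, across layers", {
  m1 <- matrix(runif(20), 5, 4); m2 <- matrix(runif(15), 5, 3)
  rownames(m1) <- rownames(m2) <- sprintf("S%d_T", 1:5)
  colnames(m1) <- paste0("a", 1:4); colnames(m2) <- paste0("b", 1:3)
  m1[, 2] <- NA          # feature missing everywhere -> feature dropped
  m2[4, 1] <- NA         # one sample missing one retained feature -> sample dropped
  ds <- multiomic_dataset(
    list(mklayer(m1, name = "x"), mklayer(m2, name = "y")),
    response = data.frame(sample_id = rownames(m1), drug = "D",
                          act_area = 1:5))
  # f_max 0.25: the fully missing feature goes, the 20%-missing feature
  # stays, so its one incomplete sample is removed instead
  out <- drop_missing(ds, f_max = 0.25)
  expect_false("a2" %in% feature_ids(out$layers$x))
  expect_true("b1" %in% feature_ids(out$layers$y))
  expect_identical(out$sample_ids, sprintf("S%d_T", c(1, 2, 3, 5)))
  # sample removed from every layer, alignment kept
  expect_identical(rownames(out$layers$x$values), rownames(out$layers$y$values))
  # clean data passes through unchanged
  ds2 <- multiomic_dataset(
    list(mklayer(matrix(runif(20), 5, 4))),
    response = data.frame(sample_id = sprintf("S%02d_T", 1:5), drug = "D",
                          act_area = 1:5))
  expect_identical(drop_missing(ds2)$layers[[1]]$values, ds2$layers[[1]]$values)
})

test_that("variance filter keeps the right count and kills flat features first", {
  set.seed(2)
  m <- matrix(rnorm(100), 10, 10)
  m[, 4] <- 3  # zero variance
  l <- mklayer(m)
  out <- variance_filter(l, 0.5)
  expect_equal(ncol(out$values), 5)
  expect_false("f04" %in% feature_ids(out))
  expect_identical(variance_filter(l, 0)$values, l$values)
  expect_error(variance_filter(l, 1), "drop_fraction")
  # minimal drop fraction still removes the zero-variance feature first
  expect_false("f04" %in% feature_ids(variance_filter(l, 0.1)))
})

test_that("correlation filter keeps the higher-variance member of a duplicate pair", {
  set.seed(3)
  base <- rnorm(50)
  m <- cbind(f1 = base, f2 = 2 * base, f3 = rnorm(50))  # f2 = scaled duplicate
  rownames(m) <- sprintf("S%02d_T", 1:50)
  out <- correlation_filter(mklayer(m), 0.95)
  expect_identical(feature_ids(out), c("f2", "f3"))  # f2 has 4x variance
  # r_max = 1: |r| > 1 impossible, identity
  expect_identical(feature_ids(correlation_filter(mklayer(m), 1)), colnames(m))
  # independent features at moderate n survive a 0.9 threshold
  set.seed(4)
  big <- mklayer(matrix(rnorm(500 * 30), 500, 30))
  expect_equal(ncol(correlation_filter(big, 0.9)$values), 30)
})

test_that("filters commute with sample permutation", {
  set.seed(5)
  l <- mklayer(matrix(rnorm(200), 20, 10))
  perm <- sample(20)
  lp <- l; lp$values <- lp$values[perm, ]
  expect_identical(feature_ids(variance_filter(l, 0.3)),
                   feature_ids(variance_filter(lp, 0.3)))
  expect_identical(feature_ids(correlation_filter(l, 0.6)),
                   feature_ids(correlation_filter(lp, 0.6)))
})

test_that("tissue extraction takes everything after the first underscore", {
  expect_identical(unname(extract_tissue("MCF7_BREAST")), "BREAST")
  expect_identical(unname(extract_tissue("HCT116_LARGE_INTESTINE")),
                   "LARGE_INTESTINE")
  expect_error(extract_tissue(c("MCF7_BREAST", "K562")), "K562")
})

test_that("tercile labeling splits 324 samples into thirds of 108", {
  set.seed(6)
  resp <- data.frame(sample_id = sprintf("S%03d_T", 1:324), drug = "D",
                     act_area = rnorm(324))
  lab <- make_labels(resp, "D")
  expect_equal(as.vector(table(lab$label)), c(108, 108, 108))
})

test_that("labeling schemes pick the documented tails", {
  resp <- data.frame(sample_id = sprintf("S%d_T", 1:9), drug = "D",
                     act_area = 1:9)
  lab <- make_labels(resp, "D")
  expect_setequal(names(lab$label)[lab$label == "resistant"],
                  sprintf("S%d_T", 1:3))
  expect_setequal(names(lab$label)[lab$label == "sensitive"],
                  sprintf("S%d_T", 7:9))

  resp2 <- data.frame(sample_id = sprintf("S%03d_T", 1:100), drug = "D",
                      act_area = runif(100))
  q <- table(make_labels(resp2, "D", scheme = "quartile")$label)
  expect_equal(as.vector(q), c(25, 50, 25))
  p <- table(make_labels(resp2, "D", scheme = "p95")$label)
  expect_equal(as.vector(p), c(47, 6, 47))

  expect_error(make_labels(data.frame(sample_id = c("a_T", "b_T", "c_T"),
                                      drug = "D", act_area = c(1, 1, 1)), "D"),
               "identical")
})

test_that("tercile class imbalance never exceeds one sample", {
  for (n in c(10, 47, 100, 323)) {
    resp <- data.frame(sample_id = sprintf("S%04d_T", seq_len(n)), drug = "D",
                       act_area = runif(n))
    tab <- table(make_labels(resp, "D")$label)
    expect_lte(abs(tab[["sensitive"]] - tab[["resistant"]]), 1)
  }
})

test_that("the preprocessing cascade is idempotent", {
  gd <- generate_dataset(small_config(seed = 13, n = 50))
  once <- preprocess_dataset(gd$dataset)
  twice <- preprocess_dataset(once)
  for (l in layer_names(once))
    expect_identical(twice$layers[[l]]$values, once$layers[[l]]$values)
  # continuous layers end in [0, 1] with no missing values
  v <- once$layers$transcriptomics$values
  expect_true(all(v >= 0 & v <= 1))
  expect_false(anyNA(v))
  # small layers (one-hot tissue) are exempt from the filters
  expect_equal(ncol(once$layers$tissue$values),
               ncol(gd$dataset$layers$tissue$values))
})
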