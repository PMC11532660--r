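# Shared fixtures, all generated in code.

# Small three-layer cohort with transcriptomics-only signal; cheap enough
# for structural tests of the whole engine.
small_config <- function(seed = 1, n = 120, effect = 1.5, markers = 3) {
  sim_config(
    n_samples = n,
    layers = data.frame(name = c("transcriptomics", "proteomics", "genomics"),
                        modality = c("continuous", "continuous", "boolean"),
                        n_features = c(80, 30, 25), stringsAsFactors = FALSE),
    markers_per_layer = c(transcriptomics = markers),
    effect_size = c(transcriptomics = effect),
    n_tissues = 5, noise_sd = 0.5, seed = seed)
}

small_dataset <- function(seed = 1, ...) {
  gd <- generate_dataset(small_config(seed = seed, ...))
  list(dataset = preprocess_dataset(gd$dataset), truth = gd$truth)
}

# Fast registry for structural engine tests (one tree-based, one linear,
# one neighbors learner).
fast_registry <- function() default_registry()[c("RFC", "Logistic", "KNN")]

# One cached small stacked run reused by several structural test files.
.small_run_cache <- new.env(parent = emptyenv())
small_stacked_run <- function() {
  if (is.null(.small_run_cache$run)) {
    sd <- small_dataset(seed = 42)
    res <- run_stacked_cv(sd$dataset, "DRUG1",
                          stack_config(n_outer = 4, n_inner = 4,
                                       n_repetitions = 2, seed = 7,
                                       registry = fast_registry()))
    .small_run_cache$run <- list(res = res, truth = sd$truth,
                                 dataset = sd$dataset)
  }
  .small_run_cache$run
}

# Separable toy for the learner conformance suite: one strong feature,
# four noise features.
toy_problem <- function(seed = 3, n = 40) {
  set.seed(seed)
  y <- factor(rep(c("resistant", "sensitive"), each = n / 2),
              levels = c("resistant", "sensitive"))
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("S%02d", seq_len(n)), paste0("f", 1:5)))
  X[, 3] <- ifelse(y == "sensitive", 2, -2) + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}
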