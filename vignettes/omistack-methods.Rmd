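---
title: "Stacked multi-omic prediction of drug sensitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked multi-omic prediction of drug sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(omistack)
```

## The problem

Cancer cell-line panels such as the CCLE pair multi-omic molecular
profiles — transcript expression (RPKM), boolean genomic alterations,
miRNA, reverse-phase protein arrays, metabolite abundances, pathway
activity scores, tissue of origin — with pharmacological response
measurements. The response of interest here is ActArea, the normalized
area over the dose-response curve: unlike an IC50 it integrates partial
responses over the whole concentration range, and larger values mean a
more sensitive cell line.

omistack implements a late-integration strategy for predicting drug
sensitivity from these profiles. Each omic layer is modeled separately
by a panel of heterogeneous classifiers ("first level"); a second-level
integrator then learns how to weigh the resulting per-layer,
per-algorithm probabilities into a single prediction. The appeal of
this stacked design is twofold: it lets every data modality contribute
through whichever algorithm suits it best, and the integrator's feature
importances directly quantify *which omic layer, analyzed by which
algorithm,* carries predictive signal for a given compound.

## Response labeling

For each drug, cell lines are ranked by ActArea and quantized into
terciles: the lowest third is labeled resistant, the highest third
sensitive, and the middle third intermediate. Intermediate lines are
excluded from all model fitting, which sharpens the contrast between
the classes and yields a balanced two-class problem. `make_labels()`
uses `k = floor(n/3)` lines in each tail, so the two fitted classes
never differ by more than one sample, and boundary ties are broken by
sample id for determinism. Two alternative schemes are provided for
sensitivity analyses: `quartile` (only the outer quartiles labeled) and
`p95` (the outer 47.5% tails labeled, 5% left out).

## Preprocessing cascade

`preprocess_dataset()` applies, in order:

1. **Log transform** of continuous layers, `log10(v + 1)`. Base 10 with
   a pseudo-count of 1 is conventional for RPKM-like data and keeps
   zeros at zero.
2. **Missing-data removal** without imputation: features missing in
   more than `f_max` of samples are dropped (default `f_max = 0`, the
   strictest reading), then any sample still carrying a missing value
   is dropped from *every* layer, restoring exact sample alignment.
3. **Variance filter**: the lowest-variance `variance_drop_fraction`
   (default 0.5) of features is removed, ranked on the log scale. The
   ordering is computed *before* min-max scaling deliberately: after a
   per-feature min-max every non-constant feature spans exactly [0, 1],
   variance differences reflect only distribution shape, and the filter
   would remove features essentially at random. On the log scale,
   biologically driven spread — including the variance contributed by a
   genuine association with response — still dominates the ranking,
   which is what makes a variance filter a sensible selection step in
   the first place. Ties are broken by feature id; zero-variance
   features always go first.
4. **Cross-correlation filter**: a greedy pass over features in
   descending-variance order drops any feature whose absolute Pearson
   correlation with an already-kept feature exceeds `correlation_max`
   (default 0.95). Deterministic, `O(kept x total)`; the
   higher-variance member of a redundant pair survives.
5. **Min-max normalization** of continuous layers to [0, 1] per
   feature; constant features map to 0.

Layers with fewer than `variance_min_features = 20` features (the
11-feature pathway-activity layer, the one-hot tissue layer) skip the
two filters — dropping half of 11 pathway scores is never what an
analyst wants — and categorical layers are exempt entirely. Boolean
layers pass through the log/min-max steps unchanged but are subject to
both filters.

The cascade stamps the dataset as `preprocessed`, so applying it twice
equals applying it once. This is a provenance property: a literal
second min-max of log-transformed data, or a second 50% variance cut,
is never the identity, and the stamp is what guarantees idempotence.

## The learner registry

Ten first-level algorithms are registered by default, each behind a
uniform fit / predict-probability / importance contract
(`default_registry()`):

| Key | Model | Backend | Importance |
|-----|-------|---------|------------|
| RFC | random forest | ranger, 100 trees | internal-node fraction |
| ET | extra-trees | ranger (extratrees split), 100 trees | node fraction |
| XGB | gradient boosting | xgboost, 50 rounds, depth 3 | node fraction |
| Ada | AdaBoost over stumps | in-package SAMME | node fraction |
| EN | elastic-net logistic | glmnet, alpha 0.5 | \|coefficients\| |
| Ridge | ridge regression classifier | glmnet (gaussian) + logistic link | \|coefficients\| |
| KNN | k-nearest neighbors, k = 5 | class | none |
| SVM | linear-kernel SVM, cost 1 | e1071 | \|weight vector\| |
| Logistic | L2 logistic regression | glmnet, alpha 0 | \|coefficients\| |
| Tree | single decision tree | rpart | node fraction |

Design notes:

* **Node-fraction importance** for tree-structured models is the number
  of internal (non-leaf) nodes splitting on a feature divided by the
  total internal node count across the ensemble, so the vector sums
  to 1. Regression-based models report raw absolute coefficients; KNN
  has no importance and contributes only combination-level signal via
  the integrator.
* **Penalized regressions** use a fixed penalty `lambda = 1/n` — the
  same effective regularization as the common scikit-learn `C = 1`
  default — rather than an internal cross-validated lambda, which
  would multiply the fit count tenfold inside an already nested CV.
* **Ridge and AdaBoost scores** are mapped to probabilities through a
  logistic (Platt) link calibrated on the training decision values; the
  SVM is calibrated the same way, which keeps it deterministic.
  Calibrating on training data can be optimistic for the calibration
  itself, but only the *ranking* enters AUROC and the integrator can
  rescale monotone inputs freely.
* **AdaBoost** is implemented in-package (discrete SAMME over decision
  stumps) with a vectorized weighted-stump search: per boosting round,
  signed sample weights are cumulated along each feature's sort order,
  so the optimal (feature, threshold, polarity) triple is found in one
  matrix pass without per-feature loops.
* Hyperparameters are modest ecosystem defaults appropriate for
  cohorts of a few hundred samples and are exposed per learner through
  the registry and the YAML config. The tenth algorithm is a plain
  decision tree, completing the 10-algorithm panel that yields 70
  (layer, algorithm) combinations over seven omic layers.

## Nested cross-validation and stacking

The engine (`run_stacked_cv()`) executes a strict two-level scheme per
drug:

1. The labeled cohort is split into 10 outer folds (~10% test each),
   stratified by class. Fold assignment balances both class and total
   fold sizes, reproducing the canonical 90/81/9 geometry: on a
   100-sample cohort every outer test set has 10 samples, every inner
   "B" set 9, every "A" set 81.
2. Within an outer fold, the training set is partitioned into 10
   disjoint B sets. For every (layer, algorithm) pair, a model fitted
   on each A set (training minus B) predicts its B set; the union over
   the 10 inner splits yields one out-of-fold probability per training
   sample and pair — the second-level feature space.
3. A second-level integrator (random forest, 500 trees, by default; L2
   logistic regression as the documented alternative) is fitted on
   those cumulated out-of-fold probabilities and predicts the outer
   fold's test samples from first-level models refitted on the whole
   training set.
4. The entire procedure is repeated `n_repetitions` times (default 10)
   with independent fold seeds; a sample's final probability is the
   mean of its test-fold predictions across repetitions. One pass
   already predicts every sample exactly once, so repetitions reduce
   fold-assignment variance rather than fill gaps; per-repetition
   traces are kept so either reading of "repeat and aggregate" can be
   recovered from the result object.

Every cell of every prediction matrix records which inner split
produced it, and `audit_leakage()` asserts *structurally* — not
statistically — that no cell was produced by a model whose training set
contained that sample. A failed first-level fit degrades to a 0.5 cell
with a loud warning instead of aborting a multi-hour run; the failure
log is retained in the result.

Because each first-level column depends only on its own layer,
`restack()` re-trains just the integrator on a column subset — this is
how single-layer comparisons (`run_single_layer_cv()` semantics) and
the random-forest versus logistic integrator comparison are computed
without refitting the first level.

The `"5x5"` preset (5 outer folds, 5 inner splits, 1 repetition) is the
reduced geometry used for the labeling-scheme and integrator
comparisons and for the package's own end-to-end validation runs.

## Importance aggregation

Within each (layer, algorithm) pair, per-feature importances from every
sub-fold fit (10 x 10 = 100 under the default geometry) are converted
to ranks — most important = rank 1, ties receiving the mean of the tied
positions, so every fold's ranks sum to `n(n+1)/2` — and averaged.
Ranks are never compared across layers, whose feature sets differ;
cross-layer statements go through the combination matrix.

`layer_importance_table()` additionally builds a consensus over
algorithms: the median of the per-algorithm average ranks. The median
is deliberate: a single decision tree uses a handful of features and
ties all others at a large rank, so a mean would let one sparse
algorithm mask agreement among the others, whereas the median rewards
features consistently ranked low by several algorithms.

`build_combination_matrix()` assembles the drugs x combinations matrix
of mean integrator importances and clusters rows and columns by UPGMA
(average linkage, `stats::hclust`) on Euclidean distance — the
clustergram that shows which omic/algorithm pairs drive which
compounds. Dendrograms export as Newick via ape.

## Evaluation

`auroc()` is the trapezoid under the empirical ROC with tied scores
grouped, which equals the tie-corrected Mann–Whitney statistic divided
by `n_pos * n_neg`; the test suite verifies this identity against
brute-force pair counting and against pROC. `balanced_accuracy()` is
the mean of sensitivity and specificity, appropriate for the class
imbalance created when a balanced cohort is subset to one tissue;
`ba_by_tissue()` masks tissues with fewer than 10 labeled cell lines
(or a single class), always reporting the class counts alongside. The
default classification threshold on aggregated probabilities is 0.5,
configurable.

## Explainable distillation

`distill()` reduces a drug's predictor to its three best-consensus-rank
features (transcriptomics by default, where the predictive signal
concentrates) and fits three interpretable candidates — linear
regression scored by its raw prediction, logistic regression, and a
depth-3 decision tree — under the same outer-fold CV geometry as the
full pipeline, keeping the candidate with the best out-of-fold AUROC
(ties resolved logistic > tree > linear). The three features are fixed
from the prior full-data importance analysis *before* this CV, exactly
as in the top-down construction it mirrors; this is a known optimistic
bias, preserved deliberately and worth remembering when reading the
selection AUROC. `partial_dependence_2d()` renders the decision
surface over two features with the third at its median, and
`evaluate_transfer()` applies a frozen model to an external cohort
(normalized but not re-filtered, so the frozen feature set is always
available).

## The synthetic generator

`generate_dataset()` emulates the structure of a CCLE-style cohort so
the whole pipeline can be validated against known ground truth without
any download:

* continuous layers are log-normal with per-feature location
  `N(1, 0.5)` and log-scale `Gamma(16, 16) + 0.1` — heavy-tailed,
  RPKM-like, with moderate dispersion heterogeneity so that planted
  biology rather than baseline dispersion dominates the variance
  ranking (the regime in which a variance filter is a sensible step);
* one boolean layer with Bernoulli features, baseline rates
  `Beta(2, 5)`;
* an 11-feature pathway-activity layer and a one-hot tissue layer;
* tissue labels drawn from a geometrically decaying multinomial (a few
  large groups, many small), so the N < 10 masking rule is exercised;
* a latent sensitivity score drives ActArea affinely plus
  `N(0, noise_sd)` noise (`noise_sd = 0.5` by default, i.e. half the
  latent's own standard deviation); dose-response curves themselves are
  not simulated;
* planted markers are shifted (continuous, log scale) or logit-shifted
  (boolean) by `effect_size` standard deviations per unit of their
  layer's latent contribution; each layer's contribution is a convex
  mix, re-scaled to unit variance, of a shared latent and a
  layer-private latent, with `redundancy` (default 0.7) setting the
  shared fraction. `redundancy = 1` reproduces the fully redundant
  regime in which single-layer models match the full stack;
  `redundancy = 0` makes layers complementary.

What the generator does *not* emulate: gene-gene covariance networks,
batch effects, tissue-specific expression programs, or any coupling
between tissue and response. Passing tests therefore demonstrate that
the machinery recovers planted signal under controlled conditions —
not that comparable AUROCs would be reached on real cell-line panels.

## Validation problem sizes

The package's end-to-end checks run on a 300-sample cohort (200
labeled) with a 2000-feature transcriptomics layer carrying five
markers at 1.5 SD plus two noise layers, under the `"5x5"` preset with
the full 10-algorithm registry — about 900 first-level fits per run —
and on a 210-sample distillation cohort with all signal in three
markers. These sizes keep a complete validation run in the minutes
range on a single core while leaving the planted-signal recovery,
null-control, stacking-dominance and integrator-equivalence properties
clearly testable.

## Numerical and degenerate-input conventions

* All stochastic components (fold assignment, every learner, the
  integrator, the generator) consume seeds derived deterministically
  from a single master seed; identical config + seed reproduces results
  bit for bit, including written fixture files.
* Constant features normalize to 0; zero-variance features correlate
  with nothing (treated as r = 0 in the correlation filter).
* All-equal ActArea cannot be ordered and is rejected; cohorts too
  small to stratify the requested fold geometry (fewer than 20 labeled
  samples, or fewer samples per class than folds) are rejected rather
  than silently reduced.
* Boundary ties in labeling and rank ties in importance use documented
  deterministic rules (sample-id order; mean tied rank).

## Known limitations

* The first-level hyperparameters are fixed defaults; no tuning is
  performed anywhere, so absolute performance on real data is likely
  understated relative to a tuned pipeline.
* Probability calibration of margin/regression learners on training
  data preserves ranking but not calibrated probability scale.
* The distillation selects features before its CV (see above).
* Repetitions are independent re-runs; samples' repeated predictions
  are averaged, not pooled at the score level.
* The generator's tissue labels are independent of response; real
  tissue-response confounding is not represented.
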