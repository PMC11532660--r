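Package: omistack
Title: Stacked Multi-Omic Ensembles for Drug-Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Late-integration stacked-generalization framework for predicting
    the drug sensitivity of cancer cell lines from multi-omic profiles.
    Per-omic first-level classifiers (random forest, extra-trees, gradient
    boosting, AdaBoost, penalized regressions, SVM, k-nearest neighbors and a
    single decision tree) feed a second-level integrator through a leak-free
    nested cross-validation engine. Includes CCLE-style GCT/CSV ingestion with
    a log/[0,1] preprocessing cascade and tercile response labeling,
    feature-importance rank aggregation with UPGMA clustergrams of
    omic-by-algorithm contributions, tissue-stratified balanced-accuracy
    evaluation, distillation of each ensemble into an explainable
    three-feature model, and a synthetic multi-omic generator with planted,
    layer-attributable sensitivity markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    glmnet,
    e1071,
    rpart,
    class,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pheatmap,
    withr
Config/testthat/edition: 3
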