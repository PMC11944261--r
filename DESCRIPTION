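Package: vfstack
Title: Stacked Meta-Learning Classification of Humphrey Visual Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying Humphrey 24-2 visual fields as
    glaucomatous or not. Implements the 24-2 grid geometry with adjacency,
    hemifields and anatomical sectors; total-deviation, pattern-deviation
    and probability-map computation against a configurable normative
    reference; five published rule-based field criteria (LoGTS, UKGTS,
    Kang, HAP2 part 1, Foster) expressed through a generic parameterised
    cluster-rule engine; a stacked weight-based meta-learning pipeline
    (multi-layer perceptron base models whose output-layer weights form
    132-dimensional meta-features for logistic-regression, gradient-boosted
    tree and MLP meta-learners); evaluation utilities (confusion-matrix
    metrics, ROC/AUC, prediction entropy, permutation importance, Wilcoxon
    comparisons); and a synthetic cohort generator with ground-truth labels
    so the whole system is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
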