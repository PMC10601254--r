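Package: pneumonet
Title: Bayesian Network Classifiers for Neonatal Pneumonia Risk in Gestational Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian network classifiers (naive Bayes, tree-augmented
    naive Bayes and the k-dependence Bayesian classifier) built from first
    principles for predicting neonatal pneumonia in pregnancies complicated by
    diabetes mellitus. Includes a synthetic cohort generator with a known
    ground-truth network, univariate screening (chi-squared and Mann-Whitney U),
    constraint-based structure learning (Grow-Shrink with G2 conditional
    independence tests) with bootstrap arc-strength averaging, and a
    confusion-matrix/ROC evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
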