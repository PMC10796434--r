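Package: dacsaug
Title: Drug Synergy Dataset Augmentation via Drug Action/Chemical Similarity
Version: 0.1.0
Authors@R:
    person("Synergy", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Expands anti-cancer drug-combination (synergy) datasets by
    single-drug substitution guided by the drug action/chemical similarity
    (DACS) score, the Euclidean combination of Tanimoto fingerprint
    similarity and target-set Matthews correlation, validated against
    Kendall tau-b agreement of monotherapy pIC50 profiles.  Includes
    threshold selection for the augmentation cutoff, classification
    dataset construction with random-stratified and tissue-held-out
    cross-validation, a scikit-learn-backed classifier harness (logistic
    regression, linear SVM, random forest, gradient boosting), a
    planted-cluster synthetic data generator, and machine-readable
    reporting of similarity curves, metric grids, and physicochemical
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: python3 with scikit-learn (classifier backend) and
    rdkit (physicochemical descriptors), both optional at install time.
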