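Package: igpa
Title: Information-Gain Proportioned Averaging Ensembles for Multiclass Classifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses class-probability outputs of multiple classifiers by
    weighting each classifier with its normalized information gain, computed
    from the binary entropy of its per-sample correctness indicator
    (Information Gain Proportioned Averaging, IGPA), and applies the rule
    hierarchically level by level (ML-IGPA). Ships the standard ensemble
    baselines (softmax averaging, majority voting, fixed-weight averaging),
    multiclass evaluation metrics including one-vs-rest specificity and
    ROC-AUC, forward passes of channel, squeeze-and-excitation and soft
    attention operators, a leakage-free lesion-grouped data splitter, and a
    synthetic classifier-prediction simulator so the whole pipeline runs
    without external data or model training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
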