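Package: spherelm
Title: Drug-Target Interaction Prediction with Screened Negatives and a
    Spherical-Search-Tuned Extreme Learning Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions from drug-drug and
    target-target similarity matrices plus a sparse binary interaction
    network. High-confidence negative pairs are screened with a
    similarity-weighted interaction-profile score, pairs are classified
    with an extreme learning machine (random hidden layer, output weights
    by Moore-Penrose pseudoinverse), and the hidden-layer weights and
    biases are tuned by a spherical-search evolutionary optimizer with
    success-history parameter adaptation whose fitness is cross-validated
    AUC/AUPR. Includes ranking metrics, stratified k-fold
    cross-validation, a tie-corrected Friedman test for comparing
    methods across datasets, a synthetic network generator with planted
    cluster structure, and readers/writers for the tab-delimited
    similarity-matrix and interaction-pair formats used by the
    gold-standard benchmark networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
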