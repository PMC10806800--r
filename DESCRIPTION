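Package: somal
Title: Atom-Level Active Learning for Site-of-Metabolism Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site-of-metabolism (SoM) prediction at the atom level with an
    active-learning loop built around a random-forest classifier on
    FAME-style atomic descriptors. Provides curation of SoM-annotated
    molecule libraries (standardization, filtering, symmetry-aware duplicate
    merging), circular atom fingerprints and per-atom descriptor vectors
    aggregated over bond-path neighborhoods, stratified and
    similarity-clustered (Butina) fold generation, uncertainty sampling with
    mini-batch and diverse mini-batch strategies, imbalanced-classification
    metrics (MCC, ROC AUC, Jaccard score, top-2 success rate), and a
    synthetic drug-like library generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
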