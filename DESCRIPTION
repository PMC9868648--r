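Package: topohist
Title: Topological and Radiomic Features for Lung Nodule Histology Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end benchmark pipeline comparing persistent-homology
    features with radiomic-style features for lung tumor histology prediction
    from CT-like volumes. Generates synthetic nodule cohorts with planted
    morphology (lobulation, internal cavities, spiculation), builds five
    filtration objects per scan (lesion grid raw/negated, boundary-box grid
    raw/negated, surface point cloud), computes persistence diagrams in
    dimensions 0-2 by cubical sublevel and Vietoris-Rips filtrations,
    vectorizes the 15 diagrams into a fixed 290-entry topological feature
    vector, and evaluates six model families under five feature-combination
    strategies (radiomic, topological, concatenated, soft-voting, stacking)
    with repeated stratified or patient-grouped cross-validation, ROC AUC and
    r-squared scoring, and a paired vote-versus-radiomic comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    ranger,
    xgboost,
    class,
    caret,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
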