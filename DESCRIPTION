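Package: brtsdm
Title: Boosted Regression Tree Ensembles for Habitat Suitability Change Attribution
Version: 0.1.0
Authors@R:
    person("Regional Climate and Health", "Modelling Group", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Species distribution modelling pipeline for gridded climate and
    land-use data. Builds bioclimatic (BIO1-BIO19), extreme-threshold (ND/LP)
    and absolute-humidity predictors over 31-year climatological windows,
    draws presence/pseudo-absence calibration samples under four background
    selection methods, fits boosted regression trees with cross-validated
    tree-count selection and an adaptive learning-rate/tree-complexity loop,
    scores models by TSS, spatial-sorting-bias corrected AUC and kappa, Brier
    skill, overall model skill and area of applicability, runs 16-member
    background-by-predictor-selection ensembles, attributes per-cell habitat
    suitability changes to climate versus land-use via constant and varying
    land-use scenario projections, and identifies the most important predictor
    (for change) per grid cell. Ships a synthetic-data generator with known
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
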