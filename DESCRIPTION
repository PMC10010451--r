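Package: rdmdyn
Title: Weighted RDM Regression and Variance Partitioning for
    Representational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing temporally resolved representational
    dissimilarity matrices (RDM movies) with weighted model-RDM
    regression. Builds per-dimension RDMs from human object labels
    (squared-difference dissimilarity) and from network layer
    activations (correlation distance), fits nonnegative L2-regularised
    weighted-RDM models with stratified image-level cross-validation and
    nested regularisation selection, partitions explained variance into
    total and unique components with nonnegative general linear models,
    and performs time-resolved group inference (Wilcoxon signed-rank,
    false-discovery-rate control across time, continuity criterion,
    onset extraction). Includes a synthetic RDM-movie generator with
    planted time-varying nonnegative mixtures for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
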