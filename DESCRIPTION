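Package: riverddcs
Title: Distance Decay of Community Similarity in River Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the distance decay of community similarity
    (DDCS) in dendritic river networks. Computes pairwise Sorensen similarity
    indices from presence/absence community tables, derives river-network
    covariates (network distance along the drainage tree, flow connection,
    Strahler order difference, precipitation difference), applies the
    network-to-Euclidean distance ratio filter, and fits a hierarchical
    Bayesian beta regression with per-community dyadic varying intercepts
    using a built-in No-U-Turn sampler. Includes synthetic dendritic-network
    generators for prior predictive checks, posterior retrodictive checks,
    parameter-recovery experiments and simulation-based calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    rjags,
    coda,
    yaml
Config/testthat/edition: 3
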