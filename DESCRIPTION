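Package: codriver
Title: Cross-Site Consensus Inference of Bacterioplankton Community
    Function Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for coupling bacterioplankton community composition and
    environmental conditions to community functions in coastal waters:
    OTU-table filtering, rarefaction, Bray-Curtis dissimilarity and
    hierarchical clustering; Biolog EcoPlate substrate-utilization scoring
    with AWCD normalization; derived bacterial rate quantities (growth
    efficiency, thymidine-based production, respiration from oxygen
    drawdown, bioavailable-DOC decay kinetics, CDOM spectral slopes);
    from-scratch permutation statistics (Mantel test, one-factor
    PERMANOVA); and a two-site LASSO with cross-site consensus filtering
    to identify credible drivers of community functions in p >> n
    settings. Includes a synthetic-data generator with planted drivers
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vegan,
    ape,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
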