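Package: vqconform
Title: Variational Quantum Sampling of 3D Genome Conformation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates ensembles of three-dimensional genome conformations
    from binary Hi-C contact maps with a variational quantum algorithm
    simulated classically. Chromatin is threaded through a cubic lattice so
    that every conformation maps to a spin string, a shallow real-amplitude
    parameterized circuit defines a generative distribution over spin
    strings, and a contact-likelihood objective with a tunable aggregation
    parameter interpolates between consensus (single-cell) and population
    (bulk) modelling. Includes exhaustive enumeration of the conformational
    universe for small polymers as a ground-truth oracle, calibration of
    contact-frequency matrices into binary targets, and a full evaluation
    suite (coverage, entropy, likelihood-ratio-by-energy-level, contact
    recovery, Dice-Sorensen indices, consensus scores, Jensen-Shannon
    divergence, paired F1 matching, and landscape ruggedness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nloptr,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2,
    tibble,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
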