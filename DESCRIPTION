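Package: ocellar
Title: Morphospace Analysis of a Hedgehog-Driven Gene Network Patterning
    the Drosophila Ocellar Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-node Hedgehog (Hh) signalling gene regulatory
    network that patterns the Drosophila ocellar region into two ocellar (OC,
    CiA-marked) domains flanking an interocellar (IOC, En-marked) domain.
    Provides a steady-state finite-difference solver on a one-dimensional
    grid with an analytic Hh gradient, Euclidean pattern-distance scoring
    against a control pattern with goodness tiers, one-at-a-time parameter
    sensitivity scans, randomized-parameter morphospace sampling of relative
    OC/IOC domain-length deviations, Bayesian-network classification of
    phenotype classes from parameter vectors with stratified cross-validation,
    species morphometry normalization, and seeded synthetic-data generators
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
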