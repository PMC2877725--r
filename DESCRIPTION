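Package: partnernet
Title: Co-Regulation Partnership Networks from Directed Regulatory Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms directed regulator-to-target interaction networks
    (transcription-factor/target or kinase/substrate edge lists) into
    undirected co-regulation "partnership" networks between regulators,
    filtered against a degree-preserving randomized null ensemble.
    Characterizes how the number of co-regulatory partners scales with the
    number of targets (linear versus exponential saturation, f(x) =
    a(1 - exp(-b x))), recalibrates bacterial networks by collapsing target
    genes to operons, and provides two explanatory models: a closed-form
    random-target-acquisition model with its Monte-Carlo oracle and a
    generative network-growth simulator with duplication and partial edge
    inheritance. Includes synthetic-data generators emulating the
    statistical structure of curated regulatory datasets, down-sampling
    robustness checks, and an end-to-end pipeline with seeded, reproducible
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
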