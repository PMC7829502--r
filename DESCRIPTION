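Package: dynmodnet
Type: Package
Title: Dynamic Multilayer Modular Analysis of Brain Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the modular organization of brain
    functional networks reconfigures over time. Builds sliding-window
    Fisher-z connectivity stacks from region-of-interest BOLD time series,
    optimizes multilayer (temporal) modularity with a generalized Louvain
    heuristic, and derives connection-stability, flexibility, cohesion and
    disjointness metrics from partition ensembles. Includes motion-based
    quality control, cognitive-score-based patient labeling, nonparametric
    group comparisons with false-discovery-rate control, covariate-adjusted
    partial correlations, and F-score feature selection with leave-one-out
    support-vector-machine classification and permutation testing. A
    synthetic-cohort generator with planted, time-varying community
    structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
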