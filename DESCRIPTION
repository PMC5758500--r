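Package: netaging
Title: Graph-Theoretic Analysis of Resting-State Functional Networks Across Age Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for graph-theoretic analysis of resting-state
    functional connectivity in two-group, two-session cohort designs. Builds
    Fisher-z connectivity matrices from ROI time series, thresholds them by
    connection density or edge-wise false discovery rate, derives consensus
    community structure via repeated Louvain optimisation with iterative
    fine-tuning and agreement-matrix consensus clustering, and computes
    modularity, global and local efficiency, participation coefficients and
    within/between-module connectivity. Statistical machinery covers
    normalized-mutual-information permutation tests of partition similarity,
    two-way mixed-model intraclass correlations for test-retest reliability,
    max-statistic family-wise error corrected group comparisons, and Spearman
    (plain and motion-partialled) associations between baseline network
    properties and early learning rates from training curves. A synthetic
    cohort generator with planted modular structure, group effects, session
    reliability and coupled learning curves makes every stage testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    tibble,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
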