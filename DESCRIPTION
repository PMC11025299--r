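Package: copritest
Title: Multiplicity-Adjusted Inference for Diagnostic Accuracy Studies
    with Co-Primary Endpoints
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simultaneous evaluation of multiple candidate index tests
    against minimal acceptance criteria for the co-primary endpoints
    sensitivity and specificity. Implements family-wise error rate
    controlling single-step multiple comparison procedures adapted to the
    intersection-union hypothesis system (unadjusted, Bonferroni, maxT
    with an estimated least-favourable-configuration correlation matrix,
    pairs bootstrap, wild bootstrap, and a Bayesian multivariate
    beta-binomial approach), multiplicity-adjusted rectangular comparison
    and confidence regions, synthetic data generators (correlated
    multivariate binary correctness indicators at least-favourable
    configurations and dichotomized multivariate binormal biomarkers),
    and a simulation engine estimating family-wise error rate and
    disjunctive power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
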