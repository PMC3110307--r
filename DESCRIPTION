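Package: matchedRD
Title: Paired Versus Independent-Samples Inference for Risk Differences in
    Propensity-Score Matched Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Monte Carlo framework for studying statistical inference about
    risk differences (absolute risk reductions) in 1:1 propensity-score
    matched samples with binary outcomes. Provides a calibrated
    confounded-data simulator with five covariate scenarios and two
    treatment-selection strengths, greedy nearest-neighbor caliper matching
    on the logit of the propensity score, paired (McNemar) and
    independent-samples (Pearson chi-squared) tests with the corresponding
    variance estimators and Wald confidence intervals, and a scenario harness
    that computes empirical type I error rates, coverage, confidence-interval
    widths and variance ratios over replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
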