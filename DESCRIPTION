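Package: mtwi
Title: Multisensory Temporal Window of Integration from Reaction Time and
    Temporal Order Judgment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating the multisensory (audiovisual)
    temporal window of integration (TWI) from two complementary psychophysical
    tasks and detecting task-demand-induced recalibration of the window.
    Implements race-model-inequality testing of redundant-signals reaction
    times across stimulus onset asynchronies (empirical CDF/quantile machinery
    with the (i - 0.5)/n plotting-position convention, the summed
    quantile-difference D statistic, a maximal-negative-dependence resampling
    null, the kill-the-twin catch-trial correction, a contiguity rule for the
    RT-defined window, and an exact group-level sign-permutation test);
    Bayesian fitting of a lapse-contaminated logistic psychometric function
    to temporal order judgment counts via coordinate-wise slice sampling,
    with threshold extraction at the 5th/95th posterior percentiles; and the
    cross-task comparison that classifies participants as showing malleable
    or non-malleable integration windows. Includes a synthetic-study
    generator (exGaussian reaction times with copula dependence and an
    optional coactivation gain; binomial temporal-order responses) with known
    ground truth, plus readers/writers for a plain-text study format and the
    original MAT-container layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
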