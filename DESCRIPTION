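Package: bymtrends
Title: Bayesian Spatiotemporal Smoothing and Trend Classification for
    Block-Level Survey Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Small-area estimation for health-survey indicators observed on
    an administrative block map over repeated survey rounds. Fits the
    Besag-York-Mollie (BYM) spatiotemporal model (binomial-logit or
    Poisson-log likelihood; intrinsic CAR spatial effect plus unstructured
    heterogeneity; state-average linear time trend with an optional
    block-by-time interaction) by an adaptive Metropolis-within-Gibbs
    sampler, compares interaction against no-interaction fits by the
    deviance information criterion, derives block-level trend odds ratios
    with 95 percent credible intervals by posterior resampling, and
    classifies each block's trend by the 97.5-percent-probability rule.
    Includes a synthetic-data generator with known truth, contiguity-graph
    construction from GeoJSON polygons or edge lists, and a config-driven
    pipeline over many indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
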