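Package: slmbeta
Title: Stochastic Logistic Model Simulation and Beta-Diversity Analysis of
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairs of microbial communities under the stochastic
    logistic model (SLM) with correlated carrying capacities, including
    Gamma-distributed stationary abundances and multinomial read sampling at a
    finite sequencing depth. Computes eight pairwise beta-diversity measures
    (Jaccard, Sorensen, Whittaker, effective Whittaker, Morisita-Horn, Horn,
    Bray-Curtis, and the dissimilarity/overlap pair used in
    dissimilarity-overlap analysis), estimates per-OTU carrying capacities and
    noise amplitudes from count time series with a sampling-corrected variance
    estimator, fits the cross-OTU truncated-lognormal carrying-capacity and
    exponential noise distributions, and infers the carrying-capacity
    correlation of a sample pair from its Spearman abundance correlation via a
    simulation-based calibration curve. Includes dissimilarity-overlap curve
    (DOC) construction with binned averaging and bootstrap slope estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
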