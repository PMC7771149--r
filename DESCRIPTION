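Package: uvrdefense
Title: Bayesian Analysis of UV-Radiation Effects on Inducible Defenses in Daphnia pulex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian models for kairomone-inducible defense traits in
    juvenile Daphnia pulex exposed to ultraviolet radiation (UVR). Provides a joint
    bivariate model of ordinal pedestal scores (cumulative-logit with two thresholds)
    and neckteeth counts (quintuple binomial with logit link) with per-mother random
    intercepts, a zero-truncated trivariate Gaussian model for body length, body width
    and tail-spine length, Markov chain Monte Carlo sampling with rank-normalized
    split-Rhat and effective-sample-size diagnostics, Savage-Dickey density-ratio
    evidence ratios, Tollrian induction scoring, landmark-based morphometry, and a
    seeded synthetic-data generator emulating a kairomone-effectivity trial and a
    two-clone factorial kairomone-by-UVR experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
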