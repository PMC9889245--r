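Package: stcar
Title: Bayesian Space-Time Conditional Autoregressive Models for Areal Count Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Bayesian Poisson lognormal models to area-by-year count
    panels with intrinsic conditional autoregressive (ICAR) spatial random
    effects, a first-order random-walk national trend, and independent
    per-area random-walk space-time interactions, by Metropolis-within-Gibbs
    MCMC. Includes a synthetic areal-panel generator with known ground truth,
    convergence and fit diagnostics (split-chain Gelman-Rubin statistic,
    WAIC, posterior predictive Bayesian p-values), and posterior inference
    products: covariate marginal effects, expected counts, hotspot
    exceedance probabilities, and area-specific time-trend classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
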