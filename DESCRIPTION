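Package: sathm
Title: Speed-Accuracy Tradeoff Hierarchical Modeling of Item Responses and Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint Bayesian modeling of binary item responses and item-level
    response times for timed tests. Implements a speed-accuracy tradeoff
    hierarchical model (SATHM) in which the probability of a correct response
    is a two-parameter logistic asymptote attenuated by an exponential
    approach term driven by the standardized residual log response time,
    together with the traditional hierarchical model (independent 2PL and
    lognormal response-time submodels, M0) and a response-moderation
    hierarchical model (RMHM). Estimation is by Metropolis-within-Gibbs
    MCMC with truncated-normal and inverse-Wishart priors; model comparison
    uses the deviance information criterion (DIC); a simulation engine and a
    parameter-recovery harness score posterior means by mean squared error
    and bias. Includes least-squares fitting of the classic exponential
    speed-accuracy tradeoff curve to condition-level accuracy data, long and
    wide CSV data import/export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
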