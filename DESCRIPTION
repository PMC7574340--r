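Package: carprev
Title: Bayesian Small-Area Prevalence Estimation with Conditional
    Autoregressive Spatial Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Small-area estimation of prevalence from areal count data
    using binomial logistic mixed models with Leroux and intrinsic
    conditional autoregressive (ICAR/BYM) spatial random effects,
    fitted by a Metropolis-within-Gibbs MCMC sampler written in C++.
    Includes Queen-contiguity adjacency construction from polygons or
    edge lists, population-weighted covariate aggregation, direct
    (crude) estimation with reporting suppression, spatial imputation
    of missing area-level covariates via a Gaussian BYM smoother,
    plug-in prediction for suppressed responses, precision diagnostics
    (coefficient-of-variation improvement, relative bias, quantile
    binning), and a synthetic-study generator emulating the structure
    of near-census early childhood development data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
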