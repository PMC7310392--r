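Package: ordgrowth
Title: Multilevel Ordinal Growth Models for Longitudinal Immunological Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level cumulative-logit growth models for longitudinal ordinal
    outcomes such as WHO immunological stages derived from CD4 cell counts.
    Fits proportional-odds and non-proportional-odds models with correlated
    random intercept and time slope, integrating the random effects out by
    adaptive Gauss-Hermite quadrature (maximum likelihood) or sampling them
    out by adaptive random-walk Metropolis (DIC). Includes a likelihood-ratio
    test of the proportional-odds assumption, a latent-scale intraclass
    correlation, exploratory factor reduction of clinical panels with varimax
    rotation, WHO CD4 staging with baseline descriptives, and a synthetic
    longitudinal cohort generator for validating every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
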