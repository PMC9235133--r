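Package: vrbayes
Title: Bayesian Variance-Ratio Animal Models for Microbial Count Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metropolis-within-Gibbs samplers for linear and zero-inflated
    Poisson mixed "animal" models parameterized directly on the ratios of
    additive-genetic, litter and cage variances to the phenotypic variance,
    with the joint prior of the ratios uniform on the unit simplex.
    Includes pedigree handling and the numerator relationship matrix
    (tabular method), Savage-Dickey density-ratio Bayes factors for null
    variance ratios computed from per-iteration conditional densities,
    deviance information criterion model comparison, Geweke convergence
    diagnostics, and a synthetic-study generator (multi-generation
    pedigrees, full-sib litters, cage assignment with littermate limits)
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
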