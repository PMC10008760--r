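Package: pumba
Title: Multivariate Hierarchical Bayesian Analysis of PET Pharmacokinetic
    Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Joint statistical analysis of all pharmacokinetic parameters
    estimated from positron emission tomography (PET) time activity curves.
    Provides forward kinetic models (one- and two-tissue compartment models and
    the simplified reference tissue model) with analytic convolution, weighted
    multi-start nonlinear least squares fitting with identifiability
    diagnostics, a multivariate hierarchical multifactor Bayesian model (PuMBA)
    for subject- and region-level partial pooling of log-scale parameters,
    univariate comparator analyses (linear mixed-effects models and per-region
    t-tests), synthetic-data generators for parameter-level and TAC-level
    simulation studies, and study-level evaluation of power, false-positive
    rate, bias and precision.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    lhs,
    lme4,
    minpack.lm,
    rjags,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    logspline,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
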