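Package: gpgrowth
Title: Hierarchical Gaussian Process Mixed-Effects Models of Microbial Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric Bayesian analysis of plate-reader growth curves.
    Models log optical density as a sum of Gaussian-process fixed effects
    (mean curve, treatment effects, two-factor interactions) and
    Gaussian-process random effects for experimental batches and replicate
    wells, fitted by a No-U-Turn Hamiltonian Monte Carlo sampler on the
    kernel hyperparameters after analytic marginalization of all latent
    functions.  Provides posterior credible bands for every effect and its
    time derivative (instantaneous growth rate), pointwise significance
    calling, variance-component decomposition, a forward simulator of the
    full generative model, and a classical logistic growth-curve baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
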