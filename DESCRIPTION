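Package: ssmcheck
Title: Estimability Diagnostics for Simple Linear Gaussian State-Space Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate, fit, and diagnose simple linear Gaussian
    state-space models (an AR(1) latent state observed with Gaussian
    measurement error). Provides an exact Kalman filter/smoother marginal
    likelihood with missing-data support, multi-start maximum-likelihood
    estimation with Wald and parametric-bootstrap confidence intervals,
    profile-likelihood and likelihood-surface estimability diagnostics,
    an ARMA(1,1) reparameterisation that quantifies parameter redundancy,
    a simulation study comparing state-recovery error under estimated
    versus true parameters, and a two-dimensional drift-correction model
    for animal-movement data with an ice-drift observation layer.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
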