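Package: dynlgcp
Title: Dynamic Log-Gaussian Cox Process Models for Spatio-Temporal Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits dynamic log-Gaussian Cox process models to spatio-temporal
    point patterns such as satellite fire detections. The log-intensity is
    decomposed into a second-order random walk trend, a lag-m seasonal
    component, a stationary AR(2) cycle, fixed covariate effects and a
    Matern spatial field with first-order autoregressive dependence in
    time. The spatial field is represented through the stochastic partial
    differential equation (SPDE) approach: a finite-element discretisation
    over a triangulated mesh turns the Matern field into a sparse-precision
    Gaussian Markov random field. Inference uses a Laplace (Gaussian)
    approximation of the latent field combined with empirical-Bayes or
    small-grid exploration of the hyperparameter posterior. A simulator
    generates point patterns with the exact generative structure of the
    model, so every stage of the pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
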