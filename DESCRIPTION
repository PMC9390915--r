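Package: sparselr
Title: Sparse Low-Rank Recurrent Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generative models, spectral theory and simulation tools for
    randomly sparsified low-rank recurrent neural networks of firing-rate
    units. Provides constructors for rank-one and Gaussian connectivity with
    Bernoulli or fixed-degree sparsity masks, closed-form predictions for the
    eigenvalue outlier and bulk spectral radius under sparsification, a
    forward-Euler rate-network simulator with latent-variable projections and
    dimensionality summaries, a classifier of autonomous dynamical regimes
    (decaying, structured stationary, chaotic) with phase diagrams over the
    connectivity variance-covariance plane, and a Go-Nogo evidence-integration
    task implemented in sparse rank-one networks with psychometric-curve
    readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, jsonlite, methods, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
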