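Package: hergfit
Title: Warm-Started Parameter Inference for the hERG Ion Channel Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and parameter inference for the Hodgkin-Huxley model
    of the hERG (rapid delayed-rectifier potassium, IKr) channel under
    piecewise-constant voltage-clamp protocols. Provides exact per-segment
    simulation of the two-gate model, physiologically constrained uniform
    prior sampling of the nine model parameters, synthetic labelled dataset
    generation with additive Gaussian recording noise, short-time Fourier
    transform spectrogram featurization, a small convolutional regressor
    that maps spectrograms to normalized parameters, and CMA-ES fitting
    warm-started from the regressor's predictions, benchmarked against
    prior-midpoint and random initialization. Posterior exploration with
    adaptive Metropolis MCMC is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
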