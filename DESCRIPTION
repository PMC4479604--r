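Package: cleftsim
Title: Monte Carlo Simulation of Glutamate Diffusion and AMPA Receptor
    Activation at Idealized Cortical Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Particle-based stochastic simulation of single-vesicle
    glutamate release into an idealized box-shaped synapse. Glutamate
    molecules follow Brownian dynamics in the extracellular space, bind to
    AMPA receptors on the postsynaptic density and to glutamate
    transporters on surrounding membranes, and receptor gating follows a
    continuous-time Markov scheme with Q10 temperature correction.
    Synapse configurations are sampled from measured cortical size
    distributions, batches of runs are reduced to peak-open-receptor
    statistics (maxOPEN, peak time, area under curve), and the package
    provides the downstream population analysis: correlation screens,
    power-law regression with held-out validation, maxOPEN distributions
    and quartiles, activation probabilities, and spatial opening maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
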