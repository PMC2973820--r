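Package: riskreach
Title: Movement Planning Under Risk with Changing Motor Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of rapid pointing experiments in which
    reward and penalty regions overlap and motor noise can be perturbed
    anisotropically. Provides expected-gain landscapes over aimpoints for
    bivariate Gaussian endpoint noise, maximum-expected-gain (MEG) aimpoints,
    simulated movement planners with circular or anisotropic internal models
    of motor variance as well as hill-climbing and continually-updating
    learners, estimation of endpoint noise models and aimpoint shifts from
    trial-level reach data, and Bayesian model comparison on the decibel
    scale, including Jeffreys-prior evidence for variance structure and its
    sequential trace over trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
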