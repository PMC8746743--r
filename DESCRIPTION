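Package: ddmrr
Title: Reward-Rate-Optimal Control Allocation in the Drift Diffusion Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how performance incentives shape cognitive
    control allocation through the lens of reward-rate optimization over
    drift-diffusion model (DDM) parameters. Provides closed-form DDM
    performance functions (expected error rate and decision time), a
    stochastic first-passage sampler, a moment-based DDM estimator, an
    effort-discounted reward-rate objective with analytic gradients,
    numerical optimization of drift rate and decision threshold under
    reward and penalty incentives, inversion of the optimality conditions
    to recover subjective reward and penalty sensitivities from behavior,
    a synthetic generator of an interval-based incentivized Stroop task,
    and an end-to-end simulation and recovery pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
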