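Package: dgpbisect
Title: Calibrate Monte Carlo Data-Generating Processes by Iterative Bisection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing parameter values of Monte Carlo
    data-generating processes so that simulated data attain user-specified
    characteristics. A generic stochastic bisection engine drives any
    monotone-in-expectation evaluator toward a target summary while
    recording a full iteration trace. Ready-made recipes cover four common
    calibration problems: the intercept of a logistic outcome model for a
    target outcome (or treatment) prevalence; the treatment log-odds ratio
    for a target marginal relative risk or risk difference defined on
    potential outcomes; a global coefficient scale for a target model
    c-statistic; and the conditional log-hazard ratio of a proportional
    hazards model, with event times generated by inverse-cumulative-hazard
    sampling, for a target marginal hazard ratio estimated by a univariate
    Cox fit on concatenated potential outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    survival,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
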