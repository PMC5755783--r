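Package: cedesign
Title: Bayesian Sample Size Determination for Cost-Effectiveness Trials
    with Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based design and analysis of two-arm
    cost-effectiveness trials in which survival times and accrued costs
    are right-censored. Implements two parametric joint models
    (Weibull survival with conditionally gamma costs, and bivariate
    normal survival and costs), censored-data likelihoods, a
    data-augmentation Markov chain Monte Carlo sampler for each model,
    the posterior incremental net monetary benefit (INMB) decision rule,
    and Monte-Carlo estimation of power and assurance curves over grids
    of sample size and willingness-to-pay, from which a target sample
    size is selected.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
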