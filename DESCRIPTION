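Package: doserr
Title: Simulation Laboratory for Shared and Unshared Dose Measurement Error
    in Radiation Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates grouped-cohort radiation dose ensembles under a
    multiplicative composite Berkson-classical measurement error model with
    shared and unshared components, generates synthetic cancer outcomes under
    a linear-quadratic excess-relative-risk model, and fits the grouped
    Poisson linear relative-risk model by four correction methods: unadjusted
    regression on surrogate doses, regression calibration, Monte Carlo
    maximum likelihood (likelihood averaging over dose realizations), and a
    Bayesian two-dimensional Monte Carlo method with Bayesian model averaging
    fitted by blocked Metropolis-Hastings sampling. Profile-likelihood and
    equal-tailed credible intervals, Brooks-Gelman-Rubin diagnostics, and a
    factorial experiment runner evaluate coverage, coefficient bias, and
    predicted relative-risk bias across error scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
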