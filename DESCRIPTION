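Package: sgais
Title: Online Marginal Likelihood Estimation by Stochastic Gradient
    Annealed Importance Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Bayesian marginal likelihood (evidence) of models
    for conditionally i.i.d. data in an online fashion. Sequential Bayesian
    updating is combined with an adaptive thermal annealing schedule driven
    by the effective sample size of incremental importance weights, and with
    stochastic gradient Hamiltonian Monte Carlo transitions whose potential
    energy is estimated on mini-batches of previously seen observations.
    Includes vanilla annealed importance sampling and nested sampling as
    reference estimators, three demonstration models (Bayesian linear
    regression with analytic evidence, multiclass logistic regression, and a
    diagonal-covariance Gaussian mixture), synthetic data generators
    including a non-stationary clustered stream for change-point detection,
    and a command-line interface for simulation, estimation and parameter
    sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    data.table,
    arrow
Config/testthat/edition: 3
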