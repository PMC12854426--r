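Package: pzapk
Title: Population Pharmacokinetics of Pyrazinamide and Weight-Band Dose
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of steady-state pyrazinamide
    pharmacokinetics in adult tuberculosis patients. Implements a
    one-compartment first-order absorption model with lean-body-weight
    allometric scaling and diabetes covariate effects on apparent clearance,
    Laplace-approximation marginal-likelihood estimation with stepwise
    covariate selection and nonparametric bootstrap, goodness-of-fit and
    prediction-corrected visual predictive checks, MAP Bayesian forecasting of
    individual exposure, and Monte Carlo probability-of-target-attainment
    simulation across WHO weight bands. A synthetic-cohort generator emulates
    the two-ethnicity sparse-sampling study design so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
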