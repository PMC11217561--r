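Package: aripopk
Title: Population Pharmacokinetics and Initial-Dose Optimization of
    Aripiprazole in Schizophrenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population-pharmacokinetic modelling of
    oral aripiprazole with a one-compartment first-order-absorption model,
    allometric body-weight scaling and a fluoxetine co-medication effect on
    apparent clearance. Provides FOCE-I estimation with an adaptive
    Gauss-Hermite quadrature cross-check, stepwise covariate selection by
    objective-function-value criteria, nonparametric bootstrap validation,
    goodness-of-fit and prediction-corrected visual-predictive-check
    diagnostics, a synthetic sparse therapeutic-drug-monitoring cohort
    generator, and Monte Carlo probability-of-target-attainment simulation
    for weight-banded initial dose recommendations against the 120-270 ng/ml
    therapeutic window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
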