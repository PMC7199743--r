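Package: torapkpd
Title: Population Pharmacokinetics and Pharmacodynamics of Oral Torasemide in Dogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic population pharmacokinetic/pharmacodynamic modelling of the
    loop diuretic torasemide after repeated oral dosing in dogs. Implements a
    two-compartment first-order-absorption model with the total clearance
    partitioned into urinary and non-urinary routes, a direct-response power model
    for daily diuresis driven by the daily quantity of torasemide excreted in
    urine, and an indirect-response turnover model for natriuresis with a
    threshold-activated reversible resistance modulator. Population parameters are
    estimated by Laplace-approximated marginal likelihood (FOCE-style) with
    exponential between-subject variability and combined proportional/additive
    residual error, fitted sequentially (PK then PD). Includes a synthetic
    crossover-trial generator emulating rich plasma sampling, interval urine
    collections and below-quantification censoring; non-compartmental summaries
    (trapezoidal AUC, accumulation ratio, dose-proportionality power fit); and
    steady-state dose-response simulation with closed-form inversion to the dose
    achieving a target daily diuresis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
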