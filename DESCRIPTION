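Package: flunixinpk
Title: Population Pharmacokinetics of Flunixin Meglumine in Pre-Wean Piglets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end population-pharmacokinetic analysis pipeline for
    flunixin meglumine administered to pre-wean piglets by the intravenous,
    intramuscular, oral, and transdermal routes. Provides a long-format PK
    dataset container with reader/writer and validation; an analytic
    two-compartment structural model with parallel first-order oral and
    lagged transdermal depot compartments; noncompartmental analysis
    (terminal-slope regression, trapezoidal AUC/AUMC, MRT, Vss) with group
    summaries; nonlinear mixed-effects estimation by a stochastic
    approximation EM (SAEM) algorithm with M3-style censored likelihood for
    observations below the limit of quantification, covariate and
    random-effect correlation screening, metabolizer classification, and
    goodness-of-fit diagnostics; a Box-Cox bodyweight sub-model; Monte-Carlo
    dose-exposure simulation against cyclooxygenase inhibition targets; and
    a synthetic study generator reproducing the trial design so that the
    whole pipeline is testable without the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
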