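Package: crohncea
Title: Cost-Utility Markov Modelling of Tight-Control Management in Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model of Crohn's disease activity for
    cost-utility analysis of tight-control (treat-to-target) versus conventional
    symptom-driven management with adalimumab, from a Canadian public-payer
    perspective. Health states are defined by Crohn's Disease Activity Index
    (CDAI) bands; weekly transition probabilities are estimated from
    longitudinal trial observations with a maximum-likelihood ordered probit
    regression, hospitalizations enter as a costed toll state via a binary
    probit risk model, and the economics layer accumulates discounted costs
    (hospitalization, adalimumab, biomarker monitoring, other direct medical,
    absenteeism) and quality-adjusted life-years. Includes deterministic
    (tornado, time-horizon) and probabilistic sensitivity analysis with
    Cholesky-correlated coefficient draws and cost-effectiveness acceptability
    curves, plus a synthetic longitudinal trial generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    zoo,
    yaml,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
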