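Package: riskhte
Title: Risk-Based Assessment of Treatment Effect Heterogeneity in
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the risk-modeling approach to heterogeneous
    treatment effects (HTE) in randomized controlled trials with a binary
    outcome: a treatment-blinded multivariable logistic risk model, a
    likelihood-ratio test of the treatment-by-linear-predictor
    interaction, quantile-based risk stratification, and absolute
    risk-difference treatment-benefit estimates overall, per risk
    stratum, and per traditional one-variable subgroup. Ships a
    configurable synthetic-trial generator emulating a large thrombolysis
    stroke trial so the whole pipeline is testable without any data
    download, plus reading/validation of patient-level trial tables,
    complete-case filtering, machine-readable reports, and
    operating-characteristic simulations for the interaction test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
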