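Package: markovcea
Title: Markov Cohort Cost-Effectiveness Models from Reconstructed Survival Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for trial-based cost-effectiveness analysis of
    oncology treatments: reconstruction of pseudo individual-patient data
    from digitized Kaplan-Meier curves and numbers-at-risk tables,
    parametric survival extrapolation over six families with AIC model
    selection, a three-state (progression-free, progressed, dead) Markov
    cohort model with time-dependent transition probabilities, discounted
    cost/QALY/ICER accounting including patient-assistance program drug
    schedules and serious-adverse-event costing, and one-way and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves and price-reduction scans. Ships the published
    survival parameterizations for first-line atezolizumab versus
    platinum-based chemotherapy in metastatic NSCLC by PD-L1 expression
    stratum, and a synthetic-data generator so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
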