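Package: oncocea
Title: Markov Cohort Cost-Effectiveness Modelling for First-Line
    Immunotherapy in Advanced Non-Squamous NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-modelling pipeline for trial-based economic
    evaluation of first-line camrelizumab plus pemetrexed-platinum
    chemotherapy versus chemotherapy alone in advanced non-squamous
    non-small-cell lung cancer. Reconstructs pseudo individual-patient
    data from digitized Kaplan-Meier curves and numbers-at-risk tables,
    fits and selects parametric survival distributions (exponential,
    Weibull, log-logistic, log-normal) by AIC/BIC, adjusts the control
    arm for within-trial treatment switching with a one-parameter
    rank-preserving structural failure time model, runs a three-state
    (progression-free, progressed, dead) Markov cohort model on 3-week
    cycles, and computes discounted costs, life-years, QALYs, ICERs,
    tornado diagrams, probabilistic sensitivity analyses and
    cost-effectiveness acceptability curves. A calibrated synthetic
    trial generator makes every stage testable without access to the
    source trial's patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
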