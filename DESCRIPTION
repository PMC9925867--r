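Package: smicea
Title: Lifetime Cost-Effectiveness of Tailored Smoking Cessation in Severe Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (current smoker, former smoker, dead) annual-cycle
    Markov cohort model for evaluating tailored smoking-cessation interventions
    in populations with severe mental illness (SMI) from a UK healthcare
    perspective. Implements SMI-specific parameter adjustments (relative
    mortality risk, odds-ratio to relative-risk conversion for comorbidity
    prevalence, weighted mental-health disutility), lifetime discounted cost
    and QALY accounting across starting ages 12-100 with population weighting,
    incremental cost-effectiveness analysis with dominance handling and net
    monetary benefit, probabilistic sensitivity analysis with moment-matched
    beta/gamma/log-normal parameter distributions and cost-effectiveness
    acceptability curves, one-way deterministic sensitivity analysis, and
    scenario analyses (self-reported effectiveness, service-utilisation costs,
    bidirectional cessation/relapse rates, restricted horizons). Ships
    synthetic reference surfaces (age/sex/smoking-status mortality, comorbidity
    prevalence, population weights) that stand in for external life-table and
    survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, ggplot2, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
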