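Package: osicea
Title: Cost-Effectiveness of Adjuvant Osimertinib in Resected EGFR-Mutant
    Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic re-implementation of a four-state, two-arm
    Markov cohort model comparing three years of adjuvant osimertinib with
    placebo in resected EGFR-mutant non-small cell lung cancer over a
    ten-year horizon. Provides reconstruction of individual patient data
    from digitized Kaplan-Meier coordinates and numbers-at-risk tables,
    parametric survival fitting over six families with AIC/BIC selection,
    proportional-hazards diagnostics, discounted cost and QALY accumulation
    split pre- and post-progression, incremental cost-effectiveness ratios,
    deterministic sensitivity sweeps over overall-survival benefit and drug
    price discounts, and probabilistic sensitivity analysis on the
    cost-effectiveness plane. A synthetic-data module generates
    right-censored survival samples and pseudo-digitized curves with known
    ground truth so every stage is testable without trial figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
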