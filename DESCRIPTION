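Package: hfcua
Title: Markov Cohort Cost-Utility Analysis of Add-On Empagliflozin in Heart Failure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multistate Markov cohort model for cost-utility analysis of
    add-on empagliflozin versus standard therapy in heart failure with reduced
    (HFrEF) and preserved (HFpEF) ejection fraction, from a Chinese healthcare
    system perspective. Implements trial-incidence to per-cycle probability
    conversion under a constant-hazard assumption, a 3-month-cycle cohort trace
    over NYHA classes with a post-discharge readmission tunnel and competing
    cardiovascular and non-cardiovascular mortality, half-cycle-corrected
    discounted cost and QALY accumulation, incremental cost-effectiveness
    ratios and net monetary benefit, one-way (tornado) sensitivity analysis,
    probabilistic sensitivity analysis with beta/gamma/Dirichlet sampling and
    cost-effectiveness acceptability curves, scenario analysis, and a
    patient-level microsimulation used as an independent cross-check of the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
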