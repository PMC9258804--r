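Package: afcua
Title: Cost-Utility Analysis of Catheter Ablation Strategies for Paroxysmal Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort model comparing cryoballoon ablation (CBA)
    with radiofrequency ablation (RFA) for paroxysmal atrial fibrillation from
    a health-system perspective. Computes discounted lifetime costs and
    quality-adjusted life years (QALYs), incremental cost-effectiveness ratios
    (ICER) and net monetary benefit; runs deterministic sensitivity analysis
    (one-way, two-way, tornado, threshold search) and probabilistic sensitivity
    analysis by Monte Carlo sampling from beta and gamma parameter
    distributions, with cost-effectiveness-plane quadrant classification and
    acceptability curves. Ships a synthetic life-table generator and the full
    published parameter set so every analysis runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
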