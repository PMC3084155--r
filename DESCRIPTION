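Package: htncea
Title: Cost-Effectiveness Markov Model of a Comprehensive Hypertension
    Programme in the Elderly
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-strategy Markov cohort model comparing a comprehensive
    hypertension management programme against usual care in patients aged 65
    and older, from a third-party payer perspective. Implements annual-cycle
    state transitions with an acute cardiovascular event sub-tree (hospital
    assistance, sudden death, case fatality), risk-stratum promotion after
    events, micro-costing with equivalent annual costs for capital items,
    discounting of costs and life-years gained, probabilistic sensitivity
    analysis over all parameter distributions, incremental cost-effectiveness
    ratios with dominance classification, cost-effectiveness acceptability
    curves, one-way/tornado sensitivity analysis and discount-rate scenario
    sweeps. Includes a parametric (Gompertz) generator for background
    non-cardiovascular mortality and an individual-level microsimulation used
    as an internal validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
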