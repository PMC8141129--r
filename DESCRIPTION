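Package: hbscreen
Title: Cost-Effectiveness Microsimulation of HbA1c Screening Intervals for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level state-transition (first-order Monte Carlo)
    simulation of HbA1c screening for type 2 diabetes in age-by-BMI strata,
    with a deterministic cohort-expectation engine, incremental
    cost-effectiveness analysis (dominance, extended dominance, ICER,
    willingness-to-pay decisions), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, synthetic Gompertz-Makeham life
    tables and incidence generators, and a built-in parameter preset for the
    twelve Japanese age-by-BMI strata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
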