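Package: lifestyleCEA
Title: Markov Cohort Cost-Effectiveness Model of Lifestyle Health
    Promotion in Mental Health Care
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness modelling of a physical
    activity and healthy eating promotion programme offered to individuals
    with mental disorders. Implements a nine-state Markov cohort model
    (at risk, type 2 diabetes, first-year and subsequent-year coronary
    heart disease, stroke and colon cancer, and death) driven by age- and
    sex-specific incidence and case-fatality probabilities, computes
    discounted quality-adjusted life years and payer-perspective costs for
    an intervention and a treatment-as-usual arm, and reports incremental
    cost-effectiveness ratios. Includes scenario analyses, one-way
    (tornado) sensitivity analysis, a probabilistic sensitivity analysis
    with gamma, beta and lognormal parameter distributions, and a
    microsimulation cross-check of the cohort engine.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
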