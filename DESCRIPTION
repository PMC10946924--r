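Package: cariestax
Title: Cost-Effectiveness Modelling of Sugar-Sweetened Beverage Taxation
    for Dental Caries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-cohort Markov modelling of the population health and
    economic impact of a 20% sugar-sweetened beverage (SSB) tax on dental
    caries. Simulates single-year age cohorts through four health states
    (caries free, dental caries, edentulism, dead), converts the tax-induced
    reduction in sugar intake into an age- and socioeconomic-quintile-specific
    reduction in caries incidence via a linear sugar-dose DMFT relationship,
    and accrues decayed teeth, disability-adjusted life years and discounted
    societal and healthcare costs. Provides probabilistic sensitivity
    analysis (incremental costs and outcomes, dominance/ICER, net monetary
    benefit, cost-effectiveness acceptability curves), an
    effectiveness-decay threshold analysis, and equity summaries across
    quintiles of area-level socioeconomic disadvantage, together with a
    synthetic-input generator for fully reproducible desk-scale runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
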