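Package: osteocea
Title: Microsimulation Cost-Effectiveness of Sequential Teriparatide/Alendronate in Osteoporosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level Markov microsimulation of osteoporotic fracture natural
    history in older Japanese women with prior vertebral fracture, comparing sequential
    daily teriparatide (2 years) followed by weekly alendronate (8 years) against
    alendronate monotherapy (10 years). Simulates annual cycles of hip and clinical
    vertebral fracture, excess post-hip mortality, medication adherence and persistence,
    post-treatment offset of efficacy, and accrual of discounted costs (public healthcare
    and long-term care sectors) and quality-adjusted life years. Provides incremental
    cost-effectiveness ratios, deterministic sensitivity analyses (one-way, teriparatide
    price sweep, joint fracture-incidence sweep, scenario analyses) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
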