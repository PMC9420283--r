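Package: dairyburden
Title: Preventive Fractions, Attributable Risk, and DALY Burden for Dairy
    Intake and Chronic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A theoretical comparative-risk pipeline linking meta-analytic
    summary relative risk estimates (SRREs) for dairy consumption to
    population burden of chronic disease. Computes preventive fractions
    Pr(1 - RR) and population attributable risk proportions (PARP) over a
    grid of exposure prevalences, applies them to cause-level
    disability-adjusted life year (DALY) totals via the WHO YLL + YLD
    decomposition, and produces fraction and burden tables with report
    writers and a golden-table regression harness. Ships a registry of
    published SRREs and US 2019 cause-level DALY totals as canonical
    fixtures, plus seeded synthetic generators (evidence bases, stratified
    DALY inputs, and individual-level cohorts) so the attributable-fraction
    algebra can be validated against microsimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
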