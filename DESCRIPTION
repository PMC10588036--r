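Package: hrcart
Title: Survival Risk Stratification Trees Split on Cox Hazard Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Risk stratification of time-to-event cohorts with a customized
    CART that splits on Cox hazard-ratio statistics, bagged variable
    selection with out-of-bag error, node-level risk metrics (incidence
    rates per 100 patient-years, node hazard ratios, the incidence-rate
    variation index, cumulative/dynamic AUC(t) and integrated AUC), and an
    incremental-biomarker-value suite (nested Cox models, Harrell's
    c-index, continuous NRI and IDI at a fixed horizon). Includes a
    synthetic heart-failure cohort generator with a planted tree-structured
    hazard, RT-qPCR relative-quantification preprocessing and screening
    filters for circulating miRNA candidates, and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
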