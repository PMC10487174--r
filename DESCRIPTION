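Package: healthindex3
Title: Three-Item Health Index from Blood Pressure Entropy, Sustained
    Attention, and Gait Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a three-item composite health index for older adults from
    resting-state beat-to-beat systolic blood pressure sample entropy, the
    number of bad performances in the Sustained Attention to Response Task
    (SART), and usual gait speed. Provides min-max normalisation against a
    reference cohort, data-driven derivation of risk-group cut-offs by a grid
    search over univariate Cox proportional-hazards models, survival-based
    evaluation (hazard ratios with right-censoring, cause-specific endpoints,
    ROC/AUC), a synthetic cohort generator with a proportional-hazards outcome
    model driven by the true index, and a command-line interface mirroring the
    compute / derive-cutoffs / evaluate / simulate workflow.
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
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
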