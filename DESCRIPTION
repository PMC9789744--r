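Package: dvospt
Title: Plateau-Time Analysis of Dynamic Vascular Optical Spectroscopy
    Cuff-Occlusion Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multi-wavelength near-infrared
    cuff-occlusion recordings of the lower extremities of peripheral
    arterial disease patients. Provides a seeded synthetic-cohort
    generator built on a modified Beer-Lambert forward model, chromophore
    unmixing back to oxy-, deoxy- and total-hemoglobin time courses,
    extraction of the plateau-time (PT) statistic from venous-occlusion
    trials, per-patient feature aggregation over foot angiosomes, Welch
    t-tests with Bonferroni correction, ROC/Youden-index cutoff
    selection, diagnostic-accuracy metrics, and a truth-table comparison
    of the optical classifier against ankle-brachial index and arterial
    duplex ultrasound assignments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
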