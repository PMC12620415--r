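Package: pawss
Title: Proximal Pulmonary Artery Wall Shear Stress Modelling and Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for evaluating proximal pulmonary artery
    wall shear stress as a biomarker of chronic thromboembolic disease.
    Generates Murray-law arterial trees, distributes and tunes three-element
    Windkessel (RCR) outflow boundary conditions against right-heart-catheter
    targets, solves pulsatile lumped-parameter (0D) hemodynamics, computes
    time-averaged wall shear stress (TAWSS) and oscillatory shear index (OSI),
    simulates three-group patient cohorts calibrated to published clinical
    summaries, and runs the nonparametric diagnostic statistics (Kruskal-Wallis,
    Dunn-Bonferroni, Spearman, ROC with Youden cutoff selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
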