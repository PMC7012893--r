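Package: behkit
Title: Analysis Toolkit for Bulk Enzyme Heterojunction Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational pipeline for DNA-framework "bulk enzyme
    heterojunction" (BEH) electrochemical biosensors: Monte-Carlo
    diffusion of an enzyme-cascade intermediate as fixed-step (Pearson)
    random walks with a first-passage stopping rule and radial density
    profiles; spatial statistics of two-species particle placements
    (heterotype nearest-neighbour distances, grid heatmaps, boxplot
    summaries); AC-voltammetry surface coverage and density-to-spacing
    conversion; log-linear sensor calibration with 3-delta detection
    limits and inverse-distance cascade-velocity models; ROC/AUC
    biomarker discrimination with cutoff metrics and marker combination;
    and seeded synthetic-data generators for point patterns, titrations
    and cohorts.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
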