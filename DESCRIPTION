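Package: fucotrait
Title: Plasma N-Glycan Antennary Fucosylation Traits as HNF1A-MODY Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of plasma N-glycan antennary fucosylation as a
    biomarker for HNF1A maturity-onset diabetes of the young (HNF1A-MODY).
    Quantifies HILIC-UHPLC fluorescence chromatograms by Gaussian fitting with
    sigma-edge integration and analyte quality gating (Gaussian peak quality,
    signal-to-noise), normalizes peak areas, computes direct fucosylation
    indexes and the derived antennary fucosylation trait, and evaluates
    biomarker performance with per-group IQR outlier screening,
    Wilcoxon-Mann-Whitney tests with Bonferroni correction, ROC curves with
    Youden-optimal cutpoints, triplicate coefficient-of-variation quality
    control, and interlaboratory Spearman concordance. A synthetic-cohort
    module emulates the study design (mutation groups, peak tables,
    chromatograms, plate triplicates, second-laboratory replicates) so the
    whole pipeline is testable without access to clinical data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
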