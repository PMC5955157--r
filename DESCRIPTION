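Package: petsubvol
Title: Longitudinal PET Metabolic Tumor Sub-Volume Delineation and Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing baseline intra-tumor 18F-FDG PET sub-volumes with
    post-treatment recurrence sub-volumes in sequential PET/CT studies of head and
    neck cancer. Provides NIfTI volume input/output on an explicit metric grid,
    mutual-information rigid registration of longitudinal scans restricted to a
    PET-derived anatomical region, fixed-percentage-of-SUVmax delineation of
    metabolic tumor volumes (MTV, SUVmean, total lesion glycolysis), five
    volume-overlap indices (Dice, Jaccard, overlap fraction, and common volume
    normalized to either lesion) with a Cohen-kappa-style concordance scale,
    cohort-level summary tables, Mann-Whitney group comparisons with
    D'Agostino-Pearson normality screening, and a seeded synthetic PET/CT phantom
    generator that emulates the statistical structure of such a clinical cohort
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
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
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
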