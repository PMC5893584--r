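Package: uromet
Title: Longitudinal Urinary Organic-Acid Metabolomics for Crossover Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal urinary organic-acid profiling
    in paired crossover intervention studies. Provides creatinine
    normalization, zero treatment, log transform and scaling, pooled-QC
    repeatability diagnostics, PCA and two-class PLS-DA with variable
    importance in projection (VIP), multilevel (within-subject) variants,
    ANOVA-simultaneous component analysis (ASCA) with permutation testing,
    PCA of the cases-by-(metabolite x time) unfolded tensor with per-time
    centroids, per-case trajectories and bi-plot metabolite ranking,
    triple-criterion biomarker selection (VIP, Wilcoxon signed-rank,
    signed fold change), Spearman correlation banding, paired-design power,
    and a synthetic crossover-study generator with recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
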