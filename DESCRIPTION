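Package: taxbridge
Title: Mapping Shotgun Metagenomic Microbial Signatures onto 16S rRNA Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bridges shotgun metagenomic and 16S rRNA amplicon sequencing so
    that a prediction model trained on shotgun taxon abundances can be applied
    to, and evaluated on, 16S data. Implements a two-step taxon harmonization
    algorithm (taxonomic rank-ladder candidate search followed by data-driven
    nearest centred-log-ratio profile selection on paired samples), the shared
    compositional preprocessing both technologies require (genome-length
    normalization, prevalence/abundance filtering, square-root
    Bayesian-multiplicative zero replacement, clr transformation), alpha
    diversity and sparsity descriptives, a performance-evaluation harness
    (Mann-Whitney AUC with stratified bootstrap confidence intervals,
    covariate-adjusted AUC via placement values, threshold confusion metrics,
    Spearman concordance, clr-PCA with out-of-sample projection, Procrustes
    ordination comparison), and a calibrated generator of paired
    shotgun/16S datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
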