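Package: msciseq
Title: Detecting Meiotic Sex Chromosome Inactivation from Stage-Enriched Spermatogenesis RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect meiotic sex chromosome inactivation (MSCI) from
    stage-enriched spermatogenesis expression data. Implements a negative
    binomial Wald test for stage contrasts with median-of-ratios
    normalization and Benjamini-Hochberg correction, Yates-corrected
    chi-square enrichment of regulated genes by chromosome class,
    matched-fraction ("filter-by-fraction") and threshold-based X-to-autosome
    expression ratio estimators with a neo-X extension, gene-age-stratified
    stage trajectories with Wilcoxon contrasts, k-means expression-profile
    clustering and reproducibility QC, and a seeded synthetic-data generator
    that emulates stage-enriched testis transcriptomes with known ground
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
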