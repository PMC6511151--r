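Package: lipidmed
Title: Genotype-Lipid Association and Mediation-Suppression Analysis for
    Candidate-SNP Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene association studies of lipid and
    oxidative-stress biomarkers, built around the four-criterion mediation
    framework in which a mediator (serum triglycerides) suppresses a
    genotype-outcome (HDL cholesterol) association. Provides covariate-adjusted
    linear-model association scans under additive or dominant genotype coding
    with Benjamini-Hochberg false-discovery-rate correction and subgroup
    stratification; Hardy-Weinberg and EM-based two-locus haplotype linkage
    disequilibrium estimation; the Sobel product-of-coefficients test with
    effect decomposition and suppression classification; cohort preprocessing
    (HOMA-IR, Friedewald LDL, exclusion filters, log transforms); and a
    synthetic genotype-phenotype cohort generator with the structural
    suppression topology, so the whole pipeline is testable without
    access to individual-level study data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
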