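Package: methylhet
Title: CpG-Island Methylation Heterogeneity and Differential Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for CpG-island-centric bisulfite sequencing
    analysis: CpG island, shore and promoter annotation from genome sequence;
    coverage-weighted feature- and tile-level methylation quantification;
    coverage-weighted Welch t-tests and Storey q-values for differentially
    methylated region (DMR) calling; Poisson-model ChIP-seq window enrichment
    and four-way chromatin-state classification; read-level epiallele
    diversity, methylation discordance and in-phase CpG correlation at
    amplicon loci; and a cross-validated random-forest predictor of CGI
    hypermethylation susceptibility with per-feature ablation. A seeded
    synthetic-data generator emulates two-condition RRBS counts, per-molecule
    amplicon methylation patterns, Poisson ChIP window counts and correlated
    CGI feature tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    Biostrings,
    randomForest,
    rpart,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
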