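Package: lncimmune
Title: Mapping lncRNA-Immune Interactions in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for characterising interactions between
    long non-coding RNAs (lncRNAs) and the tumor immune microenvironment in
    bulk RNA-seq cohorts with paired tumor/normal samples. Starting from a raw
    gene-by-sample count matrix it normalises to FPKM, calls differential
    lncRNAs with a negative-binomial Wald test, screens them for prognostic
    value with univariate Cox regression and median-split Kaplan-Meier
    comparisons, computes per-sample gene-set activity scores with a
    GSVA-style kernel-CDF rank random walk, maps each lncRNA's correlation
    partners onto hallmark and immune-process gene sets with one-sided exact
    enrichment tests, estimates immune-cell fractions from an LM22-style
    signature matrix by non-negative least squares, and correlates lncRNAs
    with immunogenomic signature scores, cell fractions and immune checkpoint
    genes. A synthetic cohort generator with planted ground truth provides an
    offline acceptance surface for every stage.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
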