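Package: cnvenrich
Title: Gene-Set Enrichment Analysis of Case-Control Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, gene annotation, and gene-set enrichment analysis
    for case-control copy-number variant (CNV) studies. Implements post-calling
    CNV cleaning (fragment joining, low-copy-repeat and probe-density filters,
    frequency filtering by reciprocal overlap, size and probe-count thresholds),
    annotation of CNVs with the genes they disrupt, a covariate-adjusted nested
    logistic regression deviance test for per-set case enrichment with one-sided
    signed-root p values, a within-stratum label permutation test for a global
    excess of enriched sets, stepwise minimal-set selection, conditional
    enrichment scans, single-gene tests, and CNV burden analyses (size versus
    genes hit). A synthetic-data module simulates genomes, probe maps, gene-set
    batteries and case-control CNV datasets with known embedded odds ratios so
    that every stage of the pipeline is testable end to end.
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
    igraph,
    IRanges,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
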