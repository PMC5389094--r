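Package: marknorm
Title: Constrained MAnorm Normalization and Co-Occupancy Analysis of Histone Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide comparison of two
    repressive histone marks (such as H2AK121ub and H3K27me3) between
    wild-type and mutant genotypes from ChIP-seq peak and read data.
    Implements nearest-downstream-gene peak annotation with a 2-kb promoter
    window, marked-gene calling by replicate intersection, M-A
    normalization with a constrained reference-peak set and robust linear
    regression, percent-of-wild-type retention classification, binned
    coverage and metagene profiling, permutation-based region-overlap
    enrichment, Fisher and hypergeometric set enrichment, and a seeded
    synthetic-data generator with a ground-truth manifest for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    MASS,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
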