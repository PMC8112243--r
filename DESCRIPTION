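Package: hervomics
Title: Locus-Specific Endogenous Retrovirus Expression and Host Gene
    Integration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating locus-specific human endogenous
    retrovirus (HERV) expression with host gene expression in case/control
    bulk RNA-seq studies. Provides expectation-maximization reassignment of
    ambiguously mapped fragments to individual HERV loci, Jaccard-similarity
    low-signal filtering with median-of-ratios normalization, a
    negative-binomial Wald test for differential expression, expanding-window
    HERV-to-gene proximity search with a rank-based distance null, permutation
    tests for cross-dataset overlap of differentially expressed feature sets,
    per-pair HERV-gene association models, and rank-based gene-set enrichment
    on importance scores. A synthetic-data generator produces two-dataset
    case/control studies with planted effects so the whole pipeline is
    testable end to end.
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
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
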