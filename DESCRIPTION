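Package: oculoprior
Title: Phenotype-Driven Prioritization of Rare Exome Variants for High Myopia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing candidate disease variants
    from multi-caller exome sequencing data of high-myopia cohorts. Merges
    per-caller VCF call sets by consensus agreement, filters annotated
    variants through a cascade of population allele frequency, functional
    impact (loss-of-function or in-silico predictor vote), and phenotype-gene
    criteria including overlap with myopia (MYP) QTL intervals, then
    characterizes the surviving gene set by hypergeometric GO/pathway
    enrichment under configurable backgrounds, eye-tissue expression
    comparison, and functional-interaction subnetwork module detection with
    linker genes. Ships a synthetic cohort generator with planted candidates
    and single-violation decoys so that every filtering decision is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
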