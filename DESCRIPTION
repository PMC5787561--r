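Package: innatesig
Title: Innate-Like T Cell Gene Signatures, E-Protein Target Calling, and
    Regulatory Network Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An integrative downstream-analysis toolkit for studying how
    E-protein transcription factors drive innate-like T cell (iNKT and
    gamma-delta NKT) developmental programs.  Derives a dual fold-change
    innate-like gene signature from expression matrices, classifies
    lineage-biased versus common dysregulation in mutant thymocyte
    populations, annotates ChIP-seq peaks to genes by strand-aware region
    categories and calls transcription-factor targets, computes anchor-gene
    correlation classes and a weighted Kolmogorov-Smirnov gene-set
    enrichment score with a permutation null, analyses TCR-alpha J-segment
    usage and junction productivity across genotypes, and assembles a typed
    regulator network exportable to SIF and GraphML.  Ships a seeded
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
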