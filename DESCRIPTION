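Package: polyplex
Title: Multi-Sample SNV Analysis for Mixed-Ploidy Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resolving species complexes that mix diploid and
    allopolyploid lineages from multi-sample variant calls. Provides hard
    filtering of SNVs and indels with auditable per-rule reasons, ploidy
    estimation from the allele-balance distribution at heterozygous sites,
    classification of low-balance positions against repeat and gene
    annotations, inference of allopolyploid parental lineages from
    group-exclusive SNVs, Nei's gene diversity, ABBA-BABA (Patterson's D)
    introgression tests with block-jackknife significance and FDR control,
    SNV pseudo-alignment construction with distance-based trees and
    bootstrap support, Structure-format subset export, and a synthetic
    species-complex simulator with known ground truth so the whole pipeline
    can be exercised and validated without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
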