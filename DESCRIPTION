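Package: sweepscan
Title: Selection-Signature Scanning of Multi-Breed SNP Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting genomic footprints of positive selection in
    diploid SNP-chip data from structured populations. Implements a
    mean-squares fixation-index (FST) estimator with sliding-window
    aggregation, windowed nucleotide diversity and between-group diversity
    differencing, empirical outlier-window calling, runs-of-homozygosity
    detection, linkage-disequilibrium decay profiling, allele-sharing
    distances with neighbour-joining trees and bootstrap support, and
    gene-overlap annotation with hypergeometric overrepresentation testing.
    A forward Wright-Fisher cohort simulator with known selected loci makes
    every stage of the pipeline testable at desk scale against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
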