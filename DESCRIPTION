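Package: micronucleaR
Title: Haplotype-Resolved Inference of Micronucleus Transcriptional Silencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers heritable transcriptional silencing of micronucleated
    chromosomes from haplotype-resolved single-cell expression tables of
    related cells (micronucleated cell, its sister, and their daughters), and
    detects persistent chromatin-accessibility suppression in clonally
    expanded populations with a GC- and accessibility-matched background-peak
    permutation test. Includes a synthetic-data module that generates gene
    catalogs, control-cell cohorts, mis-segregation family datasets and clone
    ATAC matrices with known ground truth, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Epigenetics, CopyNumberVariation,
    ATACSeq
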