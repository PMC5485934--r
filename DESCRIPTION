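Package: gapsites
Title: Validation of Splice-Junction Gap-Sites in Gapped RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts alignment-gap sites (candidate splice junctions) from
    gapped RNA-seq alignments and validates them with two quality scores: the
    gap quality score (gqs), computed from alignment evidence alone under
    saturating, monotone accumulation semantics, and the weighted gap
    information score (wgis), which additionally weighs donor/acceptor
    splice-site sequence scores and assigns a strand by comparing opposing
    acceptor-site scores. Includes exon-pair annotation with sum-of-distances
    (sod) minimisation against Ensembl-dialect GTF references, strand-corrected
    intronic-dinucleotide and sequence-logo statistics, a pluggable splice-site
    scoring model (maximum-entropy score tables or a trainable log-odds weight
    matrix), and a seeded synthetic-data generator that emits a genome, an
    annotation and pre-aligned gapped SAM reads with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
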