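Package: chromarch
Title: Integrative Hi-C and MeDIP-Seq Chromatin Architecture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for three-dimensional chromatin
    architecture and DNA methylation analysis from binned sequencing data.
    Implements iterative correction (ICE) balancing of Hi-C contact
    matrices, distance-decay and observed/expected transforms, A/B
    compartment calling from the leading eigenvector of the contact
    correlation matrix at 500 kb, directionality-index plus hidden Markov
    model TAD calling at 40 kb with boundary-strength scoring, bin-pair
    differential-interaction calling at 20 kb between replicated
    conditions, MeDIP-seq metagene profiles and differentially methylated
    region (DMR) calling, ChIP-seq peak annotation and boundary-enrichment
    statistics, and a synthetic-genome simulator that plants compartments,
    TADs, insulated boundaries, DMRs and peaks so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
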