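Package: lofprior
Title: Rare Loss-of-Function Variant Prioritization for Congenital
    Left-Sided Cardiac Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An exome-wide rare-variant prioritization pipeline for
    congenital left-sided cardiac lesions. Implements site-quality
    filtering of SNVs and indels, conservative loss-of-function (LOF)
    annotation (non-terminal-exon stopgains, all-isoform essential splice
    disruptions, all-isoform frameshifts), consensus damaging-missense
    (DNS) calling from six in-silico predictors, gene constraint via the
    ratio of observed to potential LOF alleles (OP ratio) with percentile
    ranking, tiered rarity filtering against population panels, a-priori
    candidate-gene intersection, trio-based inheritance-mode
    classification (de novo, inherited dominant, recessive, compound
    heterozygous in trans, X-linked), working-gene DNS expansion,
    known-pathogenic cross-referencing, and clinical-cohort enrichment
    statistics. Ships seeded synthetic-data generators (toy genome,
    planted variants with truth tables, simulated trios) so the whole
    funnel is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
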