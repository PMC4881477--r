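Package: SomaticConcord
Title: Concordance, Sensitivity and Mutational Burden of Somatic Calls
    Across Laboratories
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes somatic mutation call sets delivered by different
    sequencing laboratories (VCF or delimited reports), restricts them to a
    common genomic region such as a gene panel, and computes replicate
    concordance (Dice coefficient), truth-set sensitivity, cross-laboratory
    overlap partitions and per-megabase mutational burden. Includes a
    tumor-purity / variant-allele-frequency detectability model based on
    exact binomial tail probabilities, and a multi-laboratory call-set
    simulator with known truth for end-to-end validation of the pipeline
    without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, VariantDetection, Coverage, QualityControl,
    Sequencing, SomaticMutation
RoxygenNote: 7.3.3
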