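Package: famvar
Title: Family-Based Exome Variant Prioritization and Inheritance Classification
Version: 0.1.0
Authors@R:
    person("famvar", "maintainers", email = "famvar@example.org", role = c("aut", "cre"))
Description: Pedigree-aware prioritization of exome variant calls in disease
    families. Implements a multi-stage filter cascade (caller consensus,
    subtraction of variants shared with unaffected members, functional-class
    and minor-allele-frequency filters, SIFT/PolyPhen-2 deleteriousness
    banding, paternal-transmission removal), germline versus de novo
    classification of daughter-carried variants from mother/father presence,
    recurrence and sister-sharing summaries, transition/transversion spectrum
    statistics with an exact 2x2 test by hypergeometric enumeration, and
    genomic-context interval annotation (fragile sites, structural variation,
    repeats). Includes a Mendelian family simulator with known truth labels
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
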