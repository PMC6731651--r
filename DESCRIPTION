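Package: mutspectra
Title: Mutation Spectrum Analysis of Rare Variants Across Genomic
    Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tabulates 96-type trinucleotide mutation spectra from cohort
    variant calls, normalizes them by mutational opportunities, and tests
    for per-type enrichment between genomic compartments under an exact
    binomial null with Bonferroni control.  Includes window- and
    chromosome-level enrichment regressed on genomic covariates such as
    replication timing, scored-bin comparisons for recombination hotspot
    intensities, covariate-matched compartment comparisons, and a
    rare-variant cohort simulator with planted spectrum structure that
    provides ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
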