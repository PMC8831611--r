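Package: consmeth
Title: Cross-Species Methylation Array Probe Design and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing Infinium-style DNA methylation array probes
    that work across many species. Given a multiple-species sequence
    alignment anchored to a reference genome, a greedy optimizer places up
    to three degenerate bases per 50-mer probe so that the probe tolerates
    cross-species mismatches, maximizing the number of species the probe is
    expected to work in. The package also implements the accompanying array
    assembly pipeline (model-species set, coverage top-up, EPIC overlap,
    Infinium I complement, biomarker merge), in-silico bisulfite-converted
    exact mapping with uniqueness and target-CpG verification, genomic
    annotation of probe targets (nearest-TSS gene regions, interval overlap,
    fold enrichment, ortholog concordance), and a calibration benchmark
    analysis of methylation standards with known methylation proportions,
    including a synthetic calibration-data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
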