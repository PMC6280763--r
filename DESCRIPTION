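Package: cageforge
Title: CAGE Transcription Start Site Mapping, Promoter Architecture and
    Degradable-Carrier Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cap analysis of gene expression (CAGE) data: 5'-end
    counting of aligned tags into CAGE tag-supported TSSs (CTSSs),
    mismatched-G correction and PCR-duplicate collapse, power-law
    normalization onto a referent distribution, single-linkage tag
    clustering with interquantile-width promoter-shape metrics, library
    benchmarking against a reference (CTSS correlation, ROC, dominant-TSS
    distances, positional ratio heatmaps, permutation similarity testing),
    promoter-architecture sequence analysis (initiator composition,
    dinucleotide density maps, TATA-box PWM scanning, WW dinucleotide
    periodicity, interval overlays), self-organizing-map expression
    profiling with TSS-switch detection, in-silico design and digestion of
    selectively degradable carrier RNA, and a synthetic-data generator
    producing genomes, CTSS libraries and two-condition experiments with
    full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
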