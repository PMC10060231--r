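Package: meionascent
Title: Run-On-Calibrated Analysis of Nascent Transcription in Meiotic
    Prophase I
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing strand-specific nascent-transcription
    coverage (ChRO-seq/PRO-seq style) across the substages of meiotic
    prophase I. Calibrates radioactive nuclear run-on measurements against
    DNA standards and deconvolves per-stage relative transcriptional
    activity by least squares; converts activities and library sizes into
    absolute track normalization factors and DESeq2-style size factors;
    computes per-gene promoter-proximal pausing indices and post-PAS
    retention indices with strand-aware windows and eligibility filters;
    builds LZ-normalized fold-change trajectories and clusters genes into
    co-regulated pattern groups; and tests overlap and co-occurrence of
    regulatory-element and double-strand-break interval sets with
    chromosome-preserving shuffles and empirical p-values. Ships a
    synthetic-data generator with planted parameters so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
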