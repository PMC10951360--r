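Package: lrsvbench
Title: Tolerance-Parameterized Benchmarking of Long-Read Structural Variant Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for structural variant (SV) callsets from
    long-read sequencing. Implements tolerance-parameterized SV matching
    (sequence similarity p, size similarity P, reciprocal overlap O, reference
    distance r), one-to-one truth assignment with overall and genotype-aware
    precision/recall/F1, grid searches over matching tolerances, iterative
    multi-caller merging with source-caller tracking, breakend-level evaluation
    of translocations, criteria-based evaluation of inversions and duplications,
    tumor-normal somatic SV extraction with size-window merging, and orthogonal
    validation of candidate SVs by pseudo-read realignment scoring (matching
    percentage M, deletion percentage D, base shift B). A seeded synthetic-data
    generator produces references, diploid truth sets, caller-like callsets with
    controlled error structure, tumor/normal pairs, and constructed alignment
    records, so the whole pipeline is testable without external callers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
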