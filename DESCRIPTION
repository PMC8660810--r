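Package: crossoccupy
Title: Cross-Cell-Type Pioneer-Factor Occupancy and Chromatin
    Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing pioneer transcription-factor occupancy and
    chromatin accessibility across cell types from ChIP-seq and ATAC-seq
    interval data. Implements summit extension and replicate-reproducibility
    filtering of peaks, cross-condition classification into shared and
    cell-type-specific binding sites, genome-wide z-score coverage
    normalization with summit-centered profile matrices, IUPAC degenerate
    motif scanning with rank-binned motif-fraction tables, promoter-window
    genomic feature annotation, nucleosome-free ATAC fragment filtering, a
    negative-binomial likelihood-ratio test for time-course differential
    accessibility, and k-means clustering of accessibility trajectories.
    Ships a synthetic-data generator that emits ground-truth-labelled
    genomes, peak sets, fragments and count matrices so the whole pipeline
    is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
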