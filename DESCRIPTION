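Package: helipeak
Title: Peak-Feature Association, Differential Peak Strength, and IP-MS
    Enrichment for Replication-Stress ChIP-seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of ChIP-seq peak sets from studies of
    replication-fork progression: windowed association of peaks with
    genomic feature classes tested against a permutation null that
    preserves peak length, chromosome, and GC content; cross-condition
    comparison of matched peak strengths (fraction stronger, Wilcoxon
    signed-rank, Venn overlaps); Hanning-smoothed log2(IP/input) signal
    tracks; and spectral-count post-processing of immunoprecipitation
    mass spectrometry (SAINT-score filtering, NSAF and NSAF/PAX
    enrichment, S-versus-G2 phase-dependence calls). Includes a
    synthetic-data generator emulating a small multi-chromosome genome
    with spatially varying GC, annotated feature classes, planted peak
    enrichment, coverage tracks, and bait-versus-control spectral
    counts, so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
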