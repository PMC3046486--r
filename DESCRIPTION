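Package: chromalign
Title: Coordinate-Free Alignment of Chromatin Architecture Profiles
Version: 0.1.0
Authors@R:
    person("chromalign", "developers", email = "chromalign@example.org",
           role = c("aut", "cre"))
Description: Aligns binned genomic signal profiles (for example MNase-seq
    log2 nucleosome-occupancy tracks) across a set of regions without relying
    on genomic landmarks. Each region receives a frame offset and an optional
    orientation reversal chosen to maximize the shared signal pattern, using
    progressive greedy alignment seeded either by the single best region pair
    or by sampling every region as a seed. Includes sliding-window Pearson,
    Spearman and Euclidean scoring, tag-extension coverage and log2-occupancy
    track construction, fixed-resolution region matrix extraction with gap
    filtering, a coordinate-randomization validation harness, a synthetic
    chromatin-architecture generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
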