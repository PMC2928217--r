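Package: seqfoot
Title: Binary Signal Tracks and Strand-Aware Footprints for Aligned
    Sequencing Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds dense per-base pileup tracks from aligned sequencing
    fragments (SAM, BED, configurable GFF-like text, UCSC WIG) and stores
    them in a random-access binary format with a coordinate-offset header.
    Provides constant-time region lookup, per-region averaging and
    thresholding, and strand-oriented footprint (meta-profile) aggregation
    over large anchor sets, together with small analysis utilities:
    enzyme-bias rescaling of aggregate profiles, equal-count quantile
    binning, and an exact binomial enrichment test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite
Config/testthat/edition: 3
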