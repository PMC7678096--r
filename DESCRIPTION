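Package: cmbftrack
Title: Probability Calibration and Integration of Genome-Wide Coverage Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transforms genome-wide sequencing coverage tracks (ChIP-seq,
    ATAC-seq and related assays) into per-bin probabilities of true signal
    using the complement of the minimum Bayes' factor, with the local
    background estimated as a scaled sliding-window median of coverage.
    Multiple probability tracks -- replicates of one experiment or
    complementary assay types -- are integrated into a single track in
    [0,1] by per-position joint probability. Includes a validating reader
    and writer for 4-column BED and bedGraph coverage tracks, a
    deterministic synthetic-track simulator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
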