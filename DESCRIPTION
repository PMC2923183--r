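Package: aditrack
Title: Particle Tracking by Accumulative Difference Images
Version: 0.1.0
Authors@R:
    person("ADI", "Maintainers", email = "aditrack@example.org", role = c("aut", "cre"))
Description: Segmentation and tracking of point-like and cell-like fluorescent
    targets in low signal-to-noise time-lapse microscopy. Each frame is reduced
    to single-pixel target marks by a chain of size-sensitive filters (minimum
    filter, count-driven global threshold, mean filter, local-maximum
    reduction). Motion is recorded as per-pixel passage times (an accumulative
    difference image), from which trajectories are linked by a concentric
    shell search, including multi-start recovery of loops and crossings with
    paragon-table splicing. Includes time-color-coded trajectory rendering,
    Brownian diffusion-coefficient estimation from normalized displacement
    histograms, a ground-truth scene simulator, and a small command-line
    front end. Reads and writes uncompressed grayscale TIFF stacks without
    external imaging dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
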