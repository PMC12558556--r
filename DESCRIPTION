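Package: speedcells
Title: Locomotion-Speed Coding Analysis for Striatal Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how single-neuron spiking encodes locomotion
    speed. Computes speed scores (the signed peak of the cross-correlation
    between z-scored firing rate and z-scored running speed) with
    circular-shift surrogate nulls and Benjamini-Hochberg correction,
    assesses score stability across trial blocks and task conditions,
    tests per-unit firing-rate modulation by trial labels, builds
    locomotion onset/offset aligned normalized peri-event histograms, and
    decodes instantaneous speed from firing rates with cross-validated
    polynomial and ridge regression. Includes a synthetic-session
    generator with known ground truth (bout-structured speed profiles and
    speed-coupled inhomogeneous-Poisson spike trains) for validation and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
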