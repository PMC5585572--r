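Package: spikegibbs
Title: Maximum-Entropy Gibbs Analysis and Simulation of Spike Train Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and simulating binary spike rasters recorded
    from neuronal populations, e.g. retinal ganglion cells on multi-electrode
    arrays. Fits spatio-temporal maximum-entropy (Gibbs/Markov) models of
    population activity by matching empirical monomial averages, with an exact
    transfer-matrix engine for small models and Monte-Carlo estimation for
    larger ones; samples rasters from fitted or user-defined Gibbs potentials;
    provides goodness-of-fit diagnostics (Hellinger error traces,
    Kullback-Leibler estimates from block-entropy extrapolation, confidence
    plots with central-limit-theorem bounds). Also includes classical
    spike-train statistics (PSTH, inter-spike intervals, cross-correlograms),
    spike-triggered-average receptive-field estimation from stimulus image
    sequences, and a coupled discrete-time leaky integrate-and-fire retina
    simulator that turns image sequences into spike rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
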