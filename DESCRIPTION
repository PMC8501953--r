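Package: dropgate
Title: Simulation, Gating and Detection Power for Droplet Single-Cell RNA
    Profiling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for droplet-microfluidic single-cell RNA profiling assays
    in which cells are encapsulated with isothermal amplification reagents and
    read out by fluorescence. Provides a synthetic droplet-data generator with
    Poisson cell loading and known ground truth, detection of droplet events
    in multi-channel photodetector time traces, a programmatic gating cascade
    (spectral compensation, size and cell-stain gates, down-sampling and
    fold-over-median amplification thresholds), an exact binomial model of
    rare-cell detectability over cells-analyzed by prevalence grids,
    evaluation of DNA strand-displacement logic circuits (YES, NOT, OR, AND,
    AND-NOT) at Boolean and signal level, and efficiency-corrected fold
    enrichment from RT-qPCR threshold cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
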