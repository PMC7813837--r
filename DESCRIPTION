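Package: ampquant
Title: Quantal Analysis of Multichannel Amperometric Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and quantal analysis of single-vesicle amperometric
    spikes recorded on CMOS microelectrode arrays. Provides a generative
    model of exocytotic release (Gaussian vesicle diameters, cube-law
    quantal charge, Poisson event trains during stimulation), a model of
    the integrate-and-reset multiplexed readout with its band-limited
    noise floor, the derivative-threshold spike detection chain (1 Hz
    high-pass, binomial smoothing, 5-sigma derivative criterion), per-spike
    quantal metrics (peak amplitude, half-width, integrated charge,
    molecule count), detection-limit arithmetic, and the per-cell-median
    group statistics used to quantify pharmacological modulation of
    vesicular release.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
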