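Package: meacircuit
Title: Microcircuit Analysis of High-Density MEA Recordings from Hippocampal Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-density microelectrode array (MEA)
    recordings of hippocampal slices with epileptiform activity: population
    firing rates and burst staging (baseline/initiation/seizure), theta-band
    (4-8 Hz) local field potential spatial dynamics and electrode lag
    clustering, spike-theta phase locking with Rayleigh and Kuiper circular
    statistics, spike time tiling coefficient (STTC) matrices with
    hierarchical and eigendecomposition clustering, directed
    pairwise-correlation circuit inference from nearest-spike latency
    distributions with a circuit-geometry significance test, a synthetic
    recording generator with planted ground truth, and a simplified spiking
    network model of dentate gyrus granule-cell interconnectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork
Config/testthat/edition: 3
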