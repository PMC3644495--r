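Package: meaburst
Title: Network Burst Detection and Paired Pharmacology Analysis for
    Multi-Electrode Array Spike Trains
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous network activity recorded from
    neuronal cultures grown on multi-electrode arrays (MEAs). Detects
    single-channel and global (array-wide) burst events from spike tables,
    computes the standard suite of spiking and bursting measures (spikes per
    channel and per burst, active channels, burst durations, inter-spike and
    inter-burst intervals, the proportion of spikes in bursts, and
    peak-aligned network spike profiles), and performs paired drug-versus-
    control comparisons via percentage-change normalisation, exact Wilcoxon
    signed-rank tests with family-wise error control, and two-way ANOVA on
    burst profiles. Ships a hierarchical generative model of cultured-network
    spike trains (gamma-renewal global bursts, jittered per-channel burst
    trains, Poisson tonic background, amplitude mixture) with presets
    calibrated to published mature and immature cortical-culture statistics
    and drug-state transforms, so the whole pipeline is testable end to end
    without recordings.
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
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
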