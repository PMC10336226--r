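Package: ftsts
Title: Spiking-Network Simulation of Neocortical Seizures and Forced
    Temporal Spike-Time Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional excitatory-inhibitory spiking
    network of neocortical-onset seizures (conductance-based stochastic
    integrate-and-fire neurons with adaptive thresholds, slow
    after-hyperpolarization, and chloride-dependent GABA reversal) and
    implements the Forced Temporal Spike-Time Stimulation (FTSTS)
    protocol family: charge-balanced biphasic electrical pulse trains in
    four polarity pairings with configurable train-offset, and an
    optogenetic variant built on reduced Chronos and Chrimson
    channelrhodopsin photocurrent models. Trace-based Hebbian
    spike-timing-dependent plasticity on excitatory synapses provides
    the readout: stimulation efficacy is the rate of change of the
    average excitatory-to-inhibitory synaptic weight. Includes
    parameter-sweep machinery over amplitude, pulse width, frequency,
    train-offset, polarity, and stimulation overlap, with seed-averaged
    summaries and figure/table export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
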