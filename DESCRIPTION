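Package: memrc
Title: Memristor Reservoir Computing for Neural Spike-Train Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Software simulator of a reservoir-computing system built on a
    volatile (fading-memory) dynamic memristor. Provides generators for
    canonical neural firing patterns (tonic, bursting, irregular, adapting,
    transitions and multi-neuron synchronization states) rendered as square
    voltage pulse trains, a calibrated single-state-variable memristor model
    with nonlinear voltage-driven growth and spontaneous relaxation, a
    virtual-node reservoir that samples the device read current at fixed
    intervals, trained fully connected and small convolutional readout
    layers, and end-to-end experiments for firing-pattern recognition,
    streaming transition detection and synchronization-state analysis.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
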