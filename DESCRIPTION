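Package: izhnet
Title: Layered Cortical Spiking-Network Simulation and Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a layered cortical microcircuit of Izhikevich
    two-variable spiking neurons organised into excitatory and inhibitory
    groups with sparse random connectivity, exponentially decaying
    AMPA/NMDA/GABA synaptic conductances, and stochastic thalamic drive.
    Provides the variance-ratio (chi-squared) population synchrony measure
    and a connection-weight sweep experiment quantifying how network
    synchronisation grows with synaptic coupling strength, plus recorders
    for spike rasters, membrane traces and per-millisecond population rates,
    an optional rate-based Hebbian weight update, a YAML configuration
    format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
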