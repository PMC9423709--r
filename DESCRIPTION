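Package: insnet
Title: Photothermal Neuronal Network Simulation for Infrared Neural
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Conductance-based simulation of infrared neural stimulation
    (INS) via its photothermal pathway. Implements a temperature-dependent
    Hodgkin-Huxley neuron with Q10-scaled gating kinetics, a Curie-Weiss
    temperature-dependent membrane capacitance and the thermally induced
    capacitive (displacement) current, Tsodyks-Markram short-term synaptic
    dynamics with AMPA/NMDA (and GABA-A) receptor currents including the
    voltage-dependent magnesium block, and a random excitatory/inhibitory
    spiking network. Includes temperature-protocol generators (constant,
    rectangular pulse with ramped edges, saturating ramp), experiment
    runners for single neurons, synapse pairs and networks, and spike-train
    statistics (counts, inter-spike intervals, coefficient of variation,
    binned population rates, percent change) for dose-response analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
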