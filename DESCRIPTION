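Package: snnkit
Title: Spiking Neural Network Simulation with Sparse Connectivity and Trace-Based STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU reference implementation of exact-integration current-based
    leaky integrate-and-fire network simulation. Provides exact exponential
    propagators for neuron and synapse dynamics, sparse synaptic connectivity
    structures (padded ragged matrices, bitmask bitfields, column views),
    constant-time connectivity initialisation samplers based on order statistics
    and geometric skips, dendritic-delay ring buffers, trace-based
    spike-timing-dependent plasticity with an all-pairs oracle, declarative
    builders for an eight-population cortical microcircuit and a plastic
    balanced random network (including principled downscaling rules), and a
    spike-train statistics pipeline (rates, CV ISI, binned correlations,
    Freedman-Diaconis histograms, Gaussian-kernel smoothing, Kullback-Leibler
    divergence, Fano factor) for validating simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
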