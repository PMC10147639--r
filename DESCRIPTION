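Package: thetanet
Title: Stimulus-Driven Plastic Networks of Excitatory and Inhibitory Theta-Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of theta-neurons (the normal form of class-I
    excitable cells) coupled by adaptive gap-junction-like synapses. Synaptic
    weights evolve under a Hebbian phase-difference-dependent plasticity rule
    with two learning time scales (a fast, stimulus-gated rate and a slow,
    always-on rate) and optional sign constraints implementing Dale's
    principle. Provides stimulation protocols for entraining neural
    assemblies, builders for pre-trained modular weight matrices,
    Kuramoto-Daido order parameters and cluster diagnostics, stability sweeps
    for the memory capacity of the network as a function of the number of
    inhibitory neurons, and a memory-recall experiment in which only the
    inhibitory wiring retains the stored patterns.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
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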