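Package: v1plastic
Title: Plastic Spiking Network Model of V1 Layer 4 Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-driven simulation of a fully plastic spiking model of
    primary visual cortex layer 4: Poisson LGN ON/OFF input populations
    drive adaptive exponential integrate-and-fire excitatory and
    inhibitory populations, with voltage-based triplet STDP at excitatory
    synapses and homeostatic symmetric STDP at inhibitory synapses.
    Includes stimulus generation (whitened natural-scene surrogates,
    sinusoidal gratings, Gaussian noise patches) and a measurement suite
    for receptive fields, orientation tuning and bandwidth, tuning
    diversity, neuronal gain, excitation/inhibition balance, population
    sparseness, information per spike, discriminability, and linear image
    reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
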