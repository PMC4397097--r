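Package: oscnet
Title: Delay-Coupled Oscillator Networks and Phase Lead/Lag Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of delay-coupled Stuart-Landau and
    Kuramoto oscillators on inhomogeneous networks, built to study how a
    node's connectivity shapes its local dynamics and the direction of its
    phase interactions. Provides generators for random (Gilbert) and
    scale-free (configuration-model) graphs, a stochastic Euler integrator
    with per-edge conduction delays and degree-targeted coupling
    perturbation, phase-synchrony and directionality measures (mean phase
    coherence, phase lag index, directed phase lag index), comparison
    measures (symbolic transfer entropy, Granger causality), an EEG-style
    functional-network pipeline (band-pass filtering, Hilbert phases,
    PLI-thresholded graphs, Welch band amplitude, Spearman summaries), and
    numerical checks of the mean-field predictions linking node degree,
    oscillation amplitude, and phase lag.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    pracma,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
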