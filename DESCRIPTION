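Package: ghostburst
Title: Simulation and Analysis of In Vivo Burst Firing in Electrosensory Pyramidal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing in vivo-like burst firing
    ("ghostbursting") of electrosensory lateral line lobe (ELL) pyramidal
    cells. Provides a two-compartment conductance-based model with
    Markov-chain NMDA receptor kinetics, Li-Rinzel IP3-receptor calcium
    mobilisation, SK-channel coupling and 1/f^beta stochastic synaptic
    input; a modified four-variable stochastic Hindmarsh-Rose model with
    dual slow adaptation; a fixed-step Euler-Maruyama integration engine;
    spike detection, action-potential waveform feature extraction,
    interspike-interval and burst statistics; brute-force firing-regime
    mapping; multi-objective (NSGA-II) parameter fitting with a
    normalised-RMSE loss and a Kolmogorov-Smirnov acceptance gate; and
    Sobol sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
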