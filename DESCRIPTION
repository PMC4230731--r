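Package: kuranet
Title: Modular Kuramoto Networks, Critical Coupling, and EEG Functional
    Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying synchronization on two-scale (modular)
    networks of Kuramoto phase oscillators. Simulates modular networks in
    which each node is an all-to-all coupled population of oscillators and
    nodes interact through a directed, weighted adjacency matrix; solves
    the thermodynamic-limit self-consistency equations for per-node order
    parameters; computes the critical inter-node coupling at which a
    network of individually sub-critical nodes synchronizes, via both an
    eigenvalue formulation and a determinant scan; classifies networks
    into network-driven (strongly connected component present) versus
    node-driven (hierarchical flow) synchronization scenarios. Also infers
    directed weighted functional networks from multichannel
    electrophysiology-like time series using time-lagged cross-correlation
    with iterative amplitude-adjusted Fourier transform (IAAFT) surrogate
    significance testing, lag-based directionalization and indirect-edge
    pruning, and runs cohort-level statistics (Wilcoxon rank-sum tests
    with Bonferroni correction, ROC analysis) on model-based measures such
    as the critical coupling. Includes synthetic-data generators for motif
    networks, ground-truth lag-coupled recordings, and two-group network
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
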