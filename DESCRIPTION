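Package: opntda
Title: Ordinal Partition Networks and Persistent Homology for Multichannel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-embedding analysis of multichannel electrophysiological
    time series. A continuous branch embeds each time point as a vector in
    channel space and characterizes the resulting point cloud with
    Vietoris-Rips persistent homology (connected components and cycles,
    Betti curves, persistence summaries). A discrete branch converts each
    channel into an ordinal partition network - a weighted directed graph
    over permutation symbols of delay-embedded windows - and quantifies its
    state-transition structure with determinism, degeneracy, permutation
    entropy, map-equation community structure with modularity, and the
    largest Lyapunov exponent. Includes zero-phase FIR preprocessing,
    synthetic multichannel regime generators for validation, a pipeline
    orchestrator, and nonparametric group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
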