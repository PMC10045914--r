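Package: bcnscreen
Title: Boolean Control Network Simulation and In Silico Inhibition
    Screening for Macrophage Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates signed, weighted Boolean control networks of
    intracellular signaling under a synchronous threshold update rule,
    with environment (input) clamping realised through threshold
    overrides and attractor detection by Brent's cycle-finding
    algorithm. Provides a polarization index summarising inflammatory
    (M1-like) versus tissue-protective (M2-like) transcriptional
    output, exhaustive single- and double-target in silico inhibition
    screens across all input environments, a synergy index for target
    pairs, a literature-criteria verification harness, structural
    network statistics (degree distribution, power-law fit,
    betweenness centrality), and a deterministic synthetic-network
    generator for testing and benchmarking. Includes a command-line
    front end for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
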