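Package: pyrexc
Title: Ion-Channel Variant Effects on Layer V Pyramidal Cell Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced multicompartmental conductance-based simulator of layer V
    pyramidal cells together with an analysis pipeline for studying how small
    parameter variants of voltage-gated ion channels and Ca2+ transporters alter
    neuronal excitability. Implements tonic and bursting reference profiles, a
    variant downscaling scheme with threshold-amplitude conditions, four phenotype
    protocols (steady-state f-I curves, up/down-state coincidence detection,
    prepulse-mediated adaptation, and a discretized spike/Ca2+ coding-capacity
    analysis), cross-phenotype correlation analysis, and a synthetic variant-table
    generator so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
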