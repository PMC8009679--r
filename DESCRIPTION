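Package: asicvcf
Title: Kinetic Modelling and Voltage-Clamp Fluorometry Analysis of ASIC1a Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing acid-sensing ion channel (ASIC1a) gating by
    voltage-clamp fluorometry (VCF). Implements a four-state (closed, open,
    closed-desensitized, open-desensitized) two-gate Hodgkin-Huxley-style
    kinetic model of pH-dependent gating, a state-probability-weighted
    fluorescence model with empirical estimation of the per-state scaling
    factors, rise-time/decay-time trace kinetics and classification rules,
    Hill fits of pH-response curves, and a concordance analysis between
    VCF-predicted residue-pair movements and beta-carbon distance changes
    measured on structural models of the three functional states. A synthetic
    recording generator provides ground-truthed oocyte-like current and
    fluorescence traces and trimeric structure fixtures for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
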