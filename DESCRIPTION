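Package: pnadyn
Title: Coarse-Grained Dynamics and Metadynamics of PNA and PNA:RNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the conformational preferences of peptide
    nucleic acid (PNA) single strands and the stability of antiparallel
    PNA:RNA duplexes with a coarse-grained strand model.  Provides
    Watson-Crick bookkeeping for mixed PNA/RNA duplexes, nucleobase
    stacking and head-to-tail collective variables, a Langevin dynamics
    engine with an optional backbone torsional bias emulating
    gamma-backbone modification, a well-tempered metadynamics engine with
    hill bookkeeping, free-energy-surface reconstruction and reweighting,
    thermal melting analysis with per-base-pair hydrogen-bonding
    persistence, and re-annealing classification for distorted duplex
    geometries.  Analytic benchmark potentials with quadrature oracles are
    included for validating the enhanced-sampling machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
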