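Package: sydicos
Title: Diet- and Expression-Constrained Flux Simulation with Systematic
    Diet Composition Swaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for studying how
    diet composition and tissue gene expression jointly shape metabolic
    fluxes. Provides S4 containers for genome-scale metabolic models with
    SBML (Level 3, fbc) and tabular input/output, model curation (identifier
    mapping, merging, duplicate removal, elemental balance, task-preserving
    pruning, stoichiometric-consistency detection), construction of flux
    bounds from diet composition, respiratory gas exchange and gene
    expression (an adapted E-flux), flux balance analysis with secondary
    minimisation of total absolute flux on a built-in linear-programming
    engine, and the Systematic Diet Composition Swap (SyDiCoS) analysis
    layer: diet component swapping, flux distances and ratios, per-subsystem
    reaction ratios and biomass-connected differential subnetworks.
    Deterministic generators supply toy hepatic models, control/western-style
    diet fixtures and tumor/peritumoral-like expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pracma,
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
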