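Package: ncrcircuit
Title: Resource Competition and CRISPRi-Based Negatively Competitive
    Regulation in Coupled Self-Activating Gene Circuits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic modelling and measurement analysis for two-module
    synthetic gene circuits that compete for shared cellular resources.
    Implements ODE models of dual self-activation (DSA) and cascading
    bistable switch (CBS) topologies in which winner-takes-all (WTA)
    behaviour emerges from resource competition, together with a CRISPR
    interference controller in which two single guide RNAs compete for a
    limited dCas9 pool (negatively competitive regulation, NCR).  Provides
    deterministic steady-state, hysteresis and phase-diagram analyses,
    extrinsic-noise population simulation producing flow-cytometry-like
    event tables and plate-reader-like growth series, a quadrant-gating
    cytometry pipeline with singlet gating and replicate statistics, and
    seeded synthetic-data generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    deSolve,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'params.R'
    'circuit-model.R'
    'equilibria.R'
    'population.R'
    'cytometry.R'
    'synthetic.R'
    'io.R'
    'cli.R'
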