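Package: crossbeta
Title: Coarse-Grained Discrete Molecular Dynamics and Analysis of Amyloid
    Cross-Seeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for studying how short bacterial
    functional-amyloid fragments template (cross-seed) the fibrillization of
    the Alzheimer's peptide Abeta42. Provides an event-driven discrete
    molecular dynamics (DMD) engine for two-bead-per-residue peptide models
    with stepwise (square-well) potentials, directional backbone hydrogen
    bonds and a ghost-collision thermostat; a builder for ideal double-layer
    cross-beta nanofibrils with canonical interstrand/intersheet spacings;
    fragment hotspot-scanning, self-assembly and nanofibril cross-seeding
    pipelines; trajectory statistics (residue contact maps, binding
    frequencies, single-linkage cluster sizes, beta-sheet content,
    centre-of-mass distance distributions, fibril-end binding modes);
    sigmoidal thioflavin-T kinetics fitting with lag-time extraction; and
    fibril morphometry (helical pitch and height) from traced contours.
    Synthetic-data generators with known ground truth make every stage
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
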