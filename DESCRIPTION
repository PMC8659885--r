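Package: pacsab
Title: Implicit-Solvent Coarse-Grained Protein Model with Event-Driven
    Discrete Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds coarse-grained protein representations with an atomistic
    backbone and MARTINI-mapped side-chain beads, assembles discretized
    pairwise potentials combining van der Waals and implicit-solvation
    channels with tunable hydrophobicity weights and directional backbone
    hydrogen bonds, and propagates them with an exact event-driven discrete
    molecular dynamics engine (ballistic motion between instantaneous
    momentum- and energy-conserving events, Andersen-style ghost-collision
    thermostat, periodic boundaries). Includes experiment drivers for
    fixed-concentration two-molecule boxes, replica sets, restrained
    complex relaxation and force-field parameter scans, plus trajectory
    observables: monomer fraction, minimum inter-chain distance,
    intermolecular contact maps, radius of gyration, helicity, RMSD,
    dissociation curves and leader clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
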