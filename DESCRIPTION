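Package: polarbind
Title: Polarized-Charge MM/PBSA Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-state binding free-energy analysis for protein-ligand
    complexes at desk scale. Implements trajectory stability metrics
    (Kabsch superposition, RMSD, RMSF), hydrogen-bond detection with
    occupancy and Coulomb energy statistics, gas-phase molecular-mechanics
    energies, a finite-difference linear Poisson-Boltzmann solver with a
    solvent-excluded dielectric boundary, Shrake-Rupley solvent-accessible
    surface areas, normal-mode entropies, single-trajectory MM/PBSA
    assembly with per-residue decomposition, and a self-consistent
    polarized-charge fitting loop (fragment RESP charges embedded in
    Poisson-Boltzmann reaction-field surface charges). Deterministic
    synthetic fixtures (Born ions, ideal helices, a hydrogen-bonded toy
    receptor-ligand complex and jittered trajectories with scripted
    hydrogen-bond rupture) exercise every code path without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'constants.R'
    'entropy.R'
    'geometry.R'
    'hbond.R'
    'io.R'
    'mmenergy.R'
    'mmpbsa.R'
    'pipeline.R'
    'polarbind-package.R'
    'polarization.R'
    'select.R'
    'solvation.R'
    'synthetic.R'
    'trajmetrics.R'
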