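Package: ccrod
Title: Coiled-Coil Rod Models and Structural Phenotype Metrics for Myosin
    Tail Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds idealized two-chain coiled-coil backbone models of the
    beta-cardiac myosin rod from sequence and heptad register using a
    generalized Crick parameterization whose motif schedules accommodate
    skip residues and single-residue deletions (e.g. the Laing distal
    myopathy mutations A1603P and K1617del).  Computes per-residue
    coiled-coil geometry and interaction statistics over conformational
    ensembles (inter-helix distance, heptad length, inter-heptad angle,
    dihedral helicity, relative solvent accessibility, salt-bridge
    occupancy, end-to-end distance, RMSD/RMSF, leader clustering),
    quantifies circular dichroism helicity and thermal melts, summarizes
    filament morphometry and solubility, and quantifies sarcomeric
    intensity line scans.  Includes seeded synthetic-data generators for
    ensembles, CD spectra, melts, filament populations and line scans so
    the full analysis chain is testable without instruments or molecular
    dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
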