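Package: fepkin
Title: Free-Energy Perturbation Along Reaction Paths and Covalent Inhibition Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the computational analysis chain of a
    combined kinetic and QM/MM study of covalent cysteine-protease inhibition.
    Provides a toy reactive potential bilinearly coupled to a harmonic bath as
    an analytically solvable stand-in for a QM/MM engine; transition-state
    location with Hessian verification and intrinsic-reaction-coordinate
    tracing; the mass-weighted path coordinate s; a free-energy-perturbation
    estimator (Zwanzig exponential or simple-mean averaging) assembling
    free-energy profiles with barrier extraction; trajectory analyses
    (block-wise hydrogen-bond occupancy, distance histograms with mode
    detection, RMSD with Kabsch superposition, per-residue Coulomb plus
    Lennard-Jones interaction-energy decomposition); two-step irreversible
    inhibition kinetics (progress-curve fitting, K_i and k_inact estimation,
    Eyring transition-state-theory interconversion of rates and barriers); and
    seeded synthetic-data generators for every input class.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
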