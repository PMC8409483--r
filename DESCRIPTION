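Package: tautofe
Title: Alchemical and RRHO Tautomer Free Energy Calculations with
    Trainable Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes tautomeric free energy differences by relative
    alchemical free energy calculations over parameterized, differentiable
    potential energy functions.  Builds single-topology hybrid systems with
    a dummy hydrogen for a tautomer pair given as SMILES, samples the
    alchemical path with restrained BAOAB Langevin dynamics, and estimates
    endpoint free energies with a multistate Bennett acceptance ratio
    (MBAR) solver, including importance-sampling reweighting of the
    estimate to perturbed potential parameters.  Also provides quasi
    rigid-rotor harmonic-oscillator (RRHO) thermochemistry with a
    free-rotor treatment of low-lying modes and graph-automorphism
    degeneracy counting, multi-minimum Boltzmann weighting of conformer
    free energies, conformer generation and RMSD-based pruning, filtering
    of tautomer databases, and gradient-based optimization of potential
    parameters against experimental tautomer free energies by reweighting.
    Analytic harmonic benchmark systems and a synthetic-data generator make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
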