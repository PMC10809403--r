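Package: finsize
Title: Finite-Size Electrostatic Corrections and Periodic-Box Artifact
    Diagnostics for Molecular Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and correcting finite-size electrostatic
    artifacts in explicit-solvent molecular simulations that use lattice-sum
    (Ewald) electrostatics. Implements the polarization correction (periodic
    versus nonperiodic finite-difference Poisson solvation), the direct-
    interaction correction (lattice-sum versus exact Coulomb solute energies),
    a builder for charge-conserving coalchemical ion perturbations that keep
    the simulation box neutral at every alchemical coupling state, and
    ensemble diagnostics for periodic-image artifacts: minimal distance to the
    box wall, end-to-end free-energy profiles with replica confidence
    intervals, conformational basin free-energy differences, orientation maps
    on the sphere, and box-size series comparisons against the largest box.
    All test inputs are generated by deterministic fixture functions (Born
    ion, rock-salt lattice, ideal helical alanine octapeptide, two-state
    distance samplers, orientation ensembles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
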