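Package: solvens
Title: Ensemble Thermodynamics for Solvation, Tautomer and Ionization
    Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Thermodynamic post-processing of quantum-chemically derived
    solvation data. Applies linear, solvent-specific corrections to
    integral-equation excess chemical potentials using partial molar
    volumes and net charges, computes Boltzmann partition-function Gibbs
    energies over tautomer and conformer ensembles, and derives partition
    coefficients (log P), distribution coefficients at pH 7.4 (log D),
    acidity constants from a calibrated two-parameter linear model, and
    tautomerization free energies by direct and thermodynamic-cycle
    routes. Includes conformer-ensemble reduction by energy-window
    filtering and greedy RMSD clustering, least-squares calibration with
    parameter-recovery validation on synthetic data, blind-challenge
    evaluation statistics, and benchmark fixture tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
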