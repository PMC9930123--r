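Package: qmmeda
Title: Energy Decomposition Analysis of Solute-Solvent Interactions under
    QM/MM Electrostatic Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes counterpoise-corrected solute-solvent interaction
    energies into electrostatic, Pauli and polarization components from
    electron deformation densities, with polarization further split into
    induction and dispersion at second-order perturbation level.  Supports
    pure-QM, fixed-point-charge and induced-dipole (charge-pair) MM
    embeddings, closest-N water QM-region selection, QM-region-size
    convergence scans against a +/-1 kcal/mol criterion, and
    snapshot-ensemble statistics.  Includes a self-contained restricted
    Hartree-Fock backend with McMurchie-Davidson Gaussian integrals and a
    synthetic solvated-snapshot generator emulating molecular-dynamics
    output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
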