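# Energy decomposition core: electrostatic, Pauli, polarization (plus the
# induction/dispersion split from induction.R), counterpoise cross-check and
# the electron-conservation diagnostics.
#
# All components are defined from three SCF states sharing one ghost-padded
# AO frame: the complex, fragment A (solute; no MM), and fragment B (QM
# solvent with the MM embedding merged into its nuclear potential), plus the
# frozen antisymmetrised determinant built from the fragment orbitals:
#
#   E_elec = classical Coulomb interaction of the frozen A and B+MM
#            distributions (nuclear cross term, nuclear-electron both ways,
#            Hartree cross term, solute-nuclei/MM term)
#   E_Pau  = E_frozen - E_A - E_B - E_elec
#   E_pol  = E_complex - E_frozen
#   total  = E_elec + E_Pau + E_pol = E_complex - E_A - E_B  (counterpoise-
#            corrected supermolecular interaction energy)

#' Classical electrostatic interaction of the frozen fragment distributions
#'
#' @param state_a,state_b unperturbed ghost-padded fragment `scf_state`s in
#'   the complex frame (B carries the MM embedding when active).
#' @return energy in kcal/mol.
#' @export
electrostatic_energy <- function(state_a, state_b) {
  frame <- state_a$frame
  if (!identical(frame$n, state_b$frame$n)) {
    stop("fragment states live in different AO frames")
  }
  jkB <- .jk_build(frame$eri, state_b$D)
  e <- nn_cross_energy(frame, state_a$real_atoms, state_b$real_atoms) +
    sum(state_a$D * (state_b$Vnuc + state_b$Vmm)) +
    sum(state_b$D * state_a$Vnuc) +
    sum(state_a$D * jkB$J) +
    nuc_mm_energy_h(frame, state_a$real_atoms, state_b$mm_charges)
  e * HARTREE_KCAL
}

#' Pauli (exchange + repulsion) energy by energy difference
#'
#' @param frozen frozen `scf_state` from [build_frozen_state()].
#' @param state_a,state_b fragment states.
#' @param e_elec electrostatic component, kcal/mol.
#' @return energy in kcal/mol (positive at bonding distances).
#' @export
pauli_energy <- function(frozen, state_a, state_b, e_elec) {
  (frozen$energy - state_a$energy - state_b$energy) * HARTREE_KCAL - e_elec
}

#' Polarization energy (orbital relaxation from the frozen determinant)
#'
#' @param complex_state converged complex `scf_state`.
#' @param frozen frozen `scf_state`.
#' @return energy in kcal/mol (variationally non-positive).
#' @export
polarization_energy <- function(complex_state, frozen) {
  (complex_state$energy - frozen$energy) * HARTREE_KCAL
}

#' EDA run configuration
#'
#' @param basis basis-set name for [basis_spec()].
#' @param method backend method keyword (this backend: `"rhf"`).
#' @param embedding `"none"`, `"charges"` or `"charges+dipoles"`.
#' @param scf_tol_energy,scf_tol_density SCF convergence thresholds; the
#'   tight defaults make the closure residual negligible (well below
#'   1e-3 kcal/mol).
#' @param max_iter SCF iteration cap.
#' @export
eda_config <- function(basis = "sto-3g", method = "rhf",
                       embedding = c("charges+dipoles", "charges", "none"),
                       scf_tol_energy = 1e-10, scf_tol_density = 1e-8,
                       max_iter = 200L) {
  embedding <- match.arg(embedding)
  structure(list(basis = basis, method = method, embedding = embedding,
                 scf_tol_energy = scf_tol_energy,
                 scf_tol_density = scf_tol_density,
                 max_iter = as.integer(max_iter)),
            class = "eda_config")
}

#' Full QM/MM energy decomposition of a solvated snapshot
#'
#' Orchestrates the three SCF calculations (complex; solute with solvent
#' ghost basis; QM solvent with solute ghost basis and the MM embedding),
#' the frozen antisymmetrised state, the component evaluations, the
#' induction/dispersion split, and the counterpoise cross-check.
#'
#' @param snapshot a `solvated_snapshot` (see [partition_closest_n()] /
#'   [read_snapshot_bundle()]), or any list with `qm_system`, `partition`,
#'   `mm_region`.
#' @param config an [eda_config()].
#' @return an `eda_result`: components `e_elec`, `e_pauli`, `e_pol`,
#'   `e_ind`, `e_disp`, `e_total`, the supermolecular `cp_total` and
#'   `closure_residual` (kcal/mol), electron-conservation traces,
#'   an `induction_diagnostics` block and run metadata.
#' @export
assemble_eda <- function(snapshot, config = eda_config()) {
  part <- snapshot$partition
  sys <- snapshot$qm_system
  region <- snapshot$mm_region
  if (is.null(region)) region <- mm_region()
  if (config$embedding == "none") region <- mm_region()
  if (config$embedding == "charges" && !is.null(region$dipoles)) {
    region <- mm_region(region$charges,
                        expansion_separation = region$expansion_separation)
  }
  validate_embedding(region, sys$xyz)
  mm <- merged_fragment_potential(part, region)$mm_charges
  if (nrow(mm) == 0L) mm <- NULL

  basis <- basis_spec(config$basis)
  frame <- qm_frame(sys, basis)
  ia <- part$fragment_a; ib <- part$fragment_b
  tolE <- config$scf_tol_energy; tolD <- config$scf_tol_density

  scf_a <- run_scf(frame = frame, real_atoms = ia, charge = part$charge_a,
                   mm_charges = NULL, method = config$method,
                   tol_energy = tolE, tol_density = tolD,
                   max_iter = config$max_iter)
  scf_b <- run_scf(frame = frame, real_atoms = ib, charge = part$charge_b,
                   mm_charges = mm, method = config$method,
                   tol_energy = tolE, tol_density = tolD,
                   max_iter = config$max_iter)
  # complex SCF seeded with the superposition of fragment densities (also
  # selects the intended ionic configuration at large separations)
  scf_cx <- run_scf(frame = frame, charge = sys$charge, mm_charges = mm,
                    method = config$method, D_init = scf_a$D + scf_b$D,
                    tol_energy = tolE, tol_density = tolD,
                    max_iter = config$max_iter)

  # full-system core Hamiltonian and constants (embedding included)
  Hcore_full <- scf_cx$Hcore
  const_full <- scf_cx$const
  frozen <- build_frozen_state(scf_a, scf_b, Hcore_full, const_full)

  e_elec <- electrostatic_energy(scf_a, scf_b)
  e_pauli <- pauli_energy(frozen, scf_a, scf_b, e_elec)
  e_pol <- polarization_energy(scf_cx, frozen)
  e_total <- e_elec + e_pauli + e_pol
  cp_total <- (scf_cx$energy - scf_a$energy - scf_b$energy) * HARTREE_KCAL
  closure_residual <- e_total - cp_total

  # electron-conservation diagnostics
  S <- frame$S
  tr_pau <- sum((frozen$D - scf_a$D - scf_b$D) * S)
  tr_pol <- sum((scf_cx$D - frozen$D) * S)

  ind <- induction_split(scf_a, scf_b, e_pol, tol_energy = tolE,
                         tol_density = tolD, max_iter = config$max_iter)

  structure(list(
    e_elec = e_elec, e_pauli = e_pauli, e_pol = e_pol,
    e_ind = ind$e_ind, e_disp = ind$e_disp, e_total = e_total,
    cp_total = cp_total, closure_residual = closure_residual,
    trace_pauli = tr_pau, trace_pol = tr_pol,
    induction_diagnostics = ind$diagnostics,
    metadata = list(
      method = config$method, basis = config$basis,
      embedding = config$embedding,
      n_qm_waters = length(ib) %/% 3L,
      n_mm_charges = if (is.null(mm)) 0L else n_mm_atoms(region),
      provenance = snapshot$provenance,
      scf_tol_energy = config$scf_tol_energy,
      scf_tol_density = config$scf_tol_density,
      scf_iterations = c(complex = scf_cx$n_iter, fragment_a = scf_a$n_iter,
                         fragment_b = scf_b$n_iter),
      second_order_caveat = abs(ind$e_ind) > abs(e_pol))),
    class = "eda_result")
}

#' @export
print.eda_result <- function(x, ...) {
  cat("QM/MM-EDA components (kcal/mol)\n")
  cat(sprintf("  electrostatic : %12.4f\n", x$e_elec))
  cat(sprintf("  Pauli         : %12.4f\n", x$e_pauli))
  cat(sprintf("  polarization  : %12.4f\n", x$e_pol))
  cat(sprintf("    induction   : %12.4f\n", x$e_ind))
  cat(sprintf("    dispersion  : %12.4f\n", x$e_disp))
  cat(sprintf("  total         : %12.4f\n", x$e_total))
  cat(sprintf("  counterpoise supermolecular : %.4f (residual %.2e)\n",
              x$cp_total, x$closure_residual))
  invisible(x)
}

#' Serialise an EDA result to JSON
#' @param result an `eda_result`.
#' @param path output path.
#' @export
write_eda_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
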