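# Restricted Hartree-Fock backend.
#
# The EDA needs, from its electronic-structure backend: AO overlap /
# one-electron matrices under point-charge embedding, an SCF driver that
# accepts ghost atoms and a fixed external one-electron potential, total
# energies of supplied density matrices, and a frozen antisymmetrised state
# built from fragment occupied orbitals.  All of that is provided here for
# closed-shell determinants.  Density matrices are spin-summed
# (Tr(D S) = n_electrons); energies are hartree unless stated otherwise.

#' Precompute the AO frame of a geometry
#'
#' Builds the shell list for *all* atoms (so fragments computed in this
#' frame are automatically ghost-padded, i.e. counterpoise-consistent) and
#' caches overlap, kinetic and two-electron integrals, which depend only on
#' the basis, not on which atoms are real.
#'
#' @param system a [mol_system()].
#' @param basis a [basis_spec()].
#' @return object of class `qm_frame`.
#' @export
qm_frame <- function(system, basis = basis_spec()) {
  si <- build_shells(system, basis)
  ok <- .ovl_kin(si$shells)
  eri <- .eri_tensor(si$shells)
  structure(list(system = system, basis = basis, shells = si$shells,
                 atom_of_shell = si$atom_of_shell, n = si$nbf,
                 S = ok$S, T = ok$T, eri = eri),
            class = "qm_frame")
}

# <mu| sum q/|r-R| |nu> for sites given in angstrom; returns the *electron*
# potential-energy matrix, i.e. -1 x the attraction kernel.
potential_matrix <- function(frame, positions_ang, q) {
  if (length(q) == 0L) return(matrix(0, frame$n, frame$n))
  pos <- matrix(as.numeric(positions_ang), ncol = 3) / BOHR_ANG
  -.coulomb_attraction(frame$shells, pos, as.numeric(q))
}

# Nuclear-attraction matrix of a set of atoms (by index) of the frame.
nuclear_matrix <- function(frame, atom_idx) {
  if (length(atom_idx) == 0L) return(matrix(0, frame$n, frame$n))
  potential_matrix(frame,
                   frame$system$xyz[atom_idx, , drop = FALSE],
                   frame$system$Z[atom_idx])
}

# Nucleus-nucleus repulsion among atoms `idx` (hartree).
nn_energy <- function(frame, idx) {
  if (length(idx) < 2L) return(0)
  pos <- frame$system$xyz[idx, , drop = FALSE] / BOHR_ANG
  Z <- frame$system$Z[idx]
  e <- 0
  for (i in seq_along(idx)[-1]) {
    for (j in seq_len(i - 1L)) {
      e <- e + Z[i] * Z[j] / sqrt(sum((pos[i, ] - pos[j, ])^2))
    }
  }
  e
}

# Cross nucleus-nucleus repulsion between two disjoint atom sets (hartree).
nn_cross_energy <- function(frame, idx_a, idx_b) {
  if (length(idx_a) == 0L || length(idx_b) == 0L) return(0)
  pa <- frame$system$xyz[idx_a, , drop = FALSE] / BOHR_ANG
  pb <- frame$system$xyz[idx_b, , drop = FALSE] / BOHR_ANG
  .pair_coulomb(pa, frame$system$Z[idx_a], pb, frame$system$Z[idx_b])
}

# Nuclei-MM classical energy in hartree for atoms `idx` against an expanded
# charge table (angstrom, e).
nuc_mm_energy_h <- function(frame, idx, mm_charges) {
  if (length(idx) == 0L || is.null(mm_charges) || nrow(mm_charges) == 0L) {
    return(0)
  }
  pa <- frame$system$xyz[idx, , drop = FALSE] / BOHR_ANG
  pb <- as.matrix(mm_charges[, c("x", "y", "z")]) / BOHR_ANG
  .pair_coulomb(pa, frame$system$Z[idx], pb, mm_charges$q)
}

# Total electronic + constant energy of a spin-summed density D under a core
# Hamiltonian Hcore (hartree); const collects nuclear and nuclei-MM terms.
energy_of_density <- function(frame, Hcore, D, const = 0) {
  jk <- .jk_build(frame$eri, D)
  sum(D * Hcore) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K) + const
}

#' Run a restricted Hartree-Fock calculation
#'
#' SCF in the (ghost-padded) frame of a geometry: atoms outside `real_atoms`
#' contribute basis functions but no nucleus or electrons.  An MM embedding
#' enters as a fixed point-charge one-electron potential; `extra_potential`
#' accepts an arbitrary fixed AO matrix (used for constrained fragment
#' relaxation in the partner's frozen field).
#'
#' @param system a [mol_system()], or a prebuilt [qm_frame()] via `frame`.
#' @param basis a [basis_spec()].
#' @param real_atoms indices of atoms with nuclei and electrons (default all).
#' @param charge net charge of the real-atom set.
#' @param mm_charges expanded MM charge table (`x,y,z,q`, angstrom/e) or NULL.
#' @param extra_potential optional fixed AO matrix added to the core
#'   Hamiltonian (hartree); may be given in the full frame dimension even
#'   when `ao_subset` is used.
#' @param ao_subset optional AO indices restricting the variational space
#'   (e.g. a fragment's own basis functions, excluding ghost-site functions);
#'   returned matrices are embedded back into the full frame dimension.
#' @param frame reuse a precomputed [qm_frame()].
#' @param method backend method keyword; this backend resolves `"rhf"`
#'   (aliases `"hf"`, `"scf"`).
#' @param D_init optional initial spin-summed density (full frame
#'   dimension), e.g. a superposition of fragment densities.
#' @param tol_energy,tol_density SCF convergence thresholds (hartree, RMS
#'   density change).
#' @param max_iter iteration cap.
#' @return an `scf_state`: list with `energy` (hartree, includes nuclear and
#'   nuclei-MM constants and any `extra_potential` interaction), `D`
#'   (spin-summed AO density), `C_occ`, `n_electrons`, `converged`,
#'   `n_iter`, `Hcore`, `const`, and bookkeeping fields.
#' @export
run_scf <- function(system = NULL, basis = basis_spec(), real_atoms = NULL,
                    charge = NULL, mm_charges = NULL, extra_potential = NULL,
                    ao_subset = NULL, frame = NULL, method = "rhf",
                    D_init = NULL,
                    tol_energy = 1e-10, tol_density = 1e-8, max_iter = 200L) {
  if (!tolower(method) %in% c("rhf", "hf", "scf")) {
    stop("unsupported method '", method,
         "': this backend provides closed-shell RHF")
  }
  if (is.null(frame)) frame <- qm_frame(system, basis)
  sys <- frame$system
  if (is.null(real_atoms)) real_atoms <- seq_along(sys$element)
  if (is.null(charge)) charge <- sys$charge
  nelec <- sum(sys$Z[real_atoms]) - charge
  if (nelec %% 2L != 0L) {
    stop("open-shell electron count (", nelec, "): unsupported")
  }
  nocc <- nelec %/% 2L
  n <- frame$n
  Vnuc <- nuclear_matrix(frame, real_atoms)
  Vmm <- if (!is.null(mm_charges) && nrow(mm_charges) > 0L) {
    potential_matrix(frame, as.matrix(mm_charges[, c("x", "y", "z")]),
                     mm_charges$q)
  } else matrix(0, n, n)
  Hcore <- frame$T + Vnuc + Vmm
  if (!is.null(extra_potential)) Hcore <- Hcore + extra_potential
  const <- nn_energy(frame, real_atoms) +
    nuc_mm_energy_h(frame, real_atoms, mm_charges)

  # working (possibly subspace-restricted) quantities
  if (!is.null(ao_subset)) {
    idx <- as.integer(ao_subset)
    S_w <- frame$S[idx, idx, drop = FALSE]
    H_w <- Hcore[idx, idx, drop = FALSE]
    arr <- array(frame$eri, rep(n, 4))
    eri_w <- as.numeric(arr[idx, idx, idx, idx])
    n_w <- length(idx)
  } else {
    idx <- seq_len(n)
    S_w <- frame$S
    H_w <- Hcore
    eri_w <- frame$eri
    n_w <- n
  }
  embed <- function(M) {
    if (n_w == n) return(M)
    out <- matrix(0, n, ncol(M))
    out[idx, ] <- M
    out
  }
  embed_sq <- function(M) {
    if (n_w == n) return(M)
    out <- matrix(0, n, n)
    out[idx, idx] <- M
    out
  }

  es <- eigen(S_w, symmetric = TRUE)
  if (min(es$values) < max(es$values) * 1e-10) {
    stop("AO overlap is numerically singular (condition number > 1e10)")
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values), n_w) %*% t(es$vectors)
  Xi <- es$vectors %*% diag(sqrt(es$values), n_w) %*% t(es$vectors)  # S^1/2

  # level_shift > 0 raises the virtual space of the current iterate by that
  # amount (hartree) before diagonalisation; the converged fixed point is
  # unchanged but aufbau flipping between near-degenerate occupations (e.g.
  # anion HOMOs vs distant ghost-site virtuals) is suppressed.
  dens_from_fock <- function(F, Dcur = NULL, shift = 0) {
    Fp <- t(X) %*% F %*% X
    if (shift > 0 && !is.null(Dcur)) {
      Pocc <- Xi %*% (Dcur / 2) %*% Xi
      Fp <- Fp + shift * (diag(n_w) - Pocc)
    }
    ef <- eigen(Fp, symmetric = TRUE)
    # eigen() orders eigenvalues decreasing; occupy the lowest nocc orbitals
    Cocc <- X %*% ef$vectors[, order(ef$values)[seq_len(nocc)], drop = FALSE]
    list(D = 2 * Cocc %*% t(Cocc), C_occ = Cocc)
  }

  if (nocc == 0L) {
    return(structure(list(energy = const, D = matrix(0, n, n),
                          C_occ = matrix(0, n, 0), n_electrons = 0L,
                          converged = TRUE, n_iter = 0L, Hcore = Hcore,
                          const = const, frame = frame,
                          real_atoms = real_atoms, Vnuc = Vnuc, Vmm = Vmm,
                          mm_charges = mm_charges, ao_subset = ao_subset),
                     class = "scf_state"))
  }

  D_start <- if (!is.null(D_init)) D_init[idx, idx, drop = FALSE] else
    dens_from_fock(H_w)$D

  scf_attempt <- function(level_shift) {
    D <- D_start
    e_old <- Inf
    fock_hist <- list(); err_hist <- list()
    st <- NULL
    for (it in seq_len(max_iter)) {
      jk <- .jk_build(eri_w, D)
      F <- H_w + jk$J - 0.5 * jk$K
      e_el <- sum(D * H_w) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K)
      err <- F %*% D %*% S_w - S_w %*% D %*% F
      err <- t(X) %*% err %*% X
      fock_hist[[length(fock_hist) + 1L]] <- F
      err_hist[[length(err_hist) + 1L]] <- err
      if (length(fock_hist) > 8L) {
        fock_hist <- fock_hist[-1L]; err_hist <- err_hist[-1L]
      }
      # DIIS extrapolation once two Fock matrices are available
      m <- length(fock_hist)
      if (m >= 2L) {
        B <- matrix(0, m + 1L, m + 1L)
        for (i in seq_len(m)) for (j in seq_len(m)) {
          B[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
        }
        B[m + 1L, seq_len(m)] <- -1; B[seq_len(m), m + 1L] <- -1
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          F <- Reduce(`+`, Map(`*`, fock_hist, cf))
        }
      }
      st <- dens_from_fock(F, Dcur = D, shift = level_shift)
      dD <- sqrt(mean((st$D - D)^2))
      de <- abs(e_el - e_old)
      D <- st$D
      e_old <- e_el
      if (de < tol_energy && dD < tol_density && it > 1L) {
        return(list(converged = TRUE, D = D, C_occ = st$C_occ,
                    energy = e_el, n_iter = it))
      }
    }
    list(converged = FALSE, de = de, dD = dD)
  }

  res <- NULL
  for (shift in c(0, 0.5, 2.0)) {
    res <- scf_attempt(shift)
    if (res$converged) break
  }
  if (!res$converged) {
    stop("SCF failed to converge in ", max_iter,
         " iterations (dE = ", signif(res$de, 3),
         ", dD = ", signif(res$dD, 3), ")")
  }
  st <- res
  e_old <- res$energy
  it <- res$n_iter
  D <- res$D
  structure(list(energy = e_old + const, D = embed_sq(D),
                 C_occ = embed(st$C_occ),
                 n_electrons = nelec, converged = TRUE, n_iter = it,
                 Hcore = Hcore, const = const, frame = frame,
                 real_atoms = real_atoms, Vnuc = Vnuc, Vmm = Vmm,
                 mm_charges = mm_charges, ao_subset = ao_subset),
            class = "scf_state")
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<scf_state: E = %.8f hartree, %d electrons, %s in %d iter>\n",
              x$energy, x$n_electrons,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Frozen antisymmetrised state from two fragment states
#'
#' Concatenates the occupied orbitals of A and B (both expressed in the full
#' complex AO frame through their ghost-padded calculations), symmetrically
#' (Loewdin) orthogonalises them, and evaluates the full-system Hamiltonian
#' (including any embedding) over the resulting closed-shell determinant.
#'
#' @param state_a,state_b `scf_state`s of the two fragments in the same frame.
#' @param Hcore_full core Hamiltonian of the full system (with embedding).
#' @param const_full nuclear + nuclei-MM constant of the full system, hartree.
#' @return an `scf_state` (constructed, not variational) with idempotent
#'   density and `n_electrons = n_A + n_B`.
#' @export
build_frozen_state <- function(state_a, state_b, Hcore_full, const_full) {
  frame <- state_a$frame
  C <- cbind(state_a$C_occ, state_b$C_occ)
  M <- t(C) %*% frame$S %*% C
  em <- eigen(M, symmetric = TRUE)
  if (min(em$values) <= 0 || max(em$values) / min(em$values) > 1e10) {
    stop("combined occupied spaces are numerically linearly dependent ",
         "(overlap condition number > 1e10)")
  }
  Minvsqrt <- em$vectors %*% diag(1 / sqrt(em$values), nrow = length(em$values)) %*%
    t(em$vectors)
  Corth <- C %*% Minvsqrt
  D <- 2 * Corth %*% t(Corth)
  e <- energy_of_density(frame, Hcore_full, D, const_full)
  structure(list(energy = e, D = D, C_occ = Corth,
                 n_electrons = state_a$n_electrons + state_b$n_electrons,
                 converged = TRUE, n_iter = 0L, Hcore = Hcore_full,
                 const = const_full, frame = frame,
                 real_atoms = sort(c(state_a$real_atoms, state_b$real_atoms)),
                 Vnuc = NULL, Vmm = NULL),
            class = "scf_state")
}

#' Relax one fragment in the frozen field of its partner
#'
#' Re-solves the fragment SCF with the partner's frozen electrostatic
#' potential (nuclear attraction + Hartree potential of the partner's
#' unperturbed density, plus the MM potential when the partner carries the
#' embedding) added as a fixed one-electron operator.  The fragment
#' polarization density is `relaxed$D - own_state$D`.
#'
#' @param own_state the fragment's unperturbed `scf_state`.
#' @param partner_potential fixed AO matrix of the partner's frozen
#'   potential (hartree), e.g. from [fragment_potential_matrix()].
#' @param tol_energy,tol_density,max_iter SCF controls.
#' @return relaxed `scf_state` (its `energy` includes the interaction with
#'   the partner potential and the fragment's own constants).
#' @export
relax_fragment_in_partner_field <- function(own_state, partner_potential,
                                            tol_energy = 1e-10,
                                            tol_density = 1e-8,
                                            max_iter = 200L) {
  frame <- own_state$frame
  run_scf(frame = frame, real_atoms = own_state$real_atoms,
          charge = sum(frame$system$Z[own_state$real_atoms]) -
            own_state$n_electrons,
          mm_charges = own_state$mm_charges,
          extra_potential = partner_potential,
          ao_subset = own_state$ao_subset,
          tol_energy = tol_energy, tol_density = tol_density,
          max_iter = max_iter)
}

#' Frozen electrostatic potential matrix of a fragment
#'
#' v_F = nuclear attraction of F's nuclei + Hartree potential of F's
#' unperturbed density (+ MM point-charge potential when `include_mm`),
#' as an AO matrix in the shared frame.
#'
#' @param state the fragment's unperturbed `scf_state`.
#' @param include_mm include the fragment's attached MM potential.
#' @return AO matrix (hartree).
#' @export
fragment_potential_matrix <- function(state, include_mm = TRUE) {
  jk <- .jk_build(state$frame$eri, state$D)
  V <- state$Vnuc + jk$J
  if (include_mm && !is.null(state$Vmm)) V <- V + state$Vmm
  V
}

#' Dipole moment of an SCF state
#'
#' mu = sum_I Z_I R_I - Tr(D r) over the state's real atoms, about the
#' origin of the frame.
#'
#' @param state an `scf_state`.
#' @return length-3 numeric, e angstrom.
#' @export
dipole_moment <- function(state) {
  frame <- state$frame
  M <- .dipole_matrices(frame$shells)
  nuc <- c(0, 0, 0)
  for (i in state$real_atoms) {
    nuc <- nuc + frame$system$Z[i] * frame$system$xyz[i, ] / BOHR_ANG
  }
  el <- c(sum(state$D * M$x), sum(state$D * M$y), sum(state$D * M$z))
  as.numeric((nuc - el) * BOHR_ANG)
}
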