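# Published minimal-basis restricted Hartree-Fock reference energies used
# below (hartree): He atom -2.807784; H2 at R = 1.4 bohr -1.1167 (with the
# standard scaled hydrogen exponents); Li+ -7.135448.

test_that("SCF reproduces published minimal-basis reference energies", {
  he <- run_scf(mol_system("He", matrix(0, 1, 3)))
  expect_equal(he$energy, -2.807784, tolerance = 1e-6)
  h2 <- run_scf(mol_system(c("H", "H"),
                           rbind(c(0, 0, 0), c(1.4 * 0.529177210903, 0, 0))))
  expect_equal(h2$energy, -1.1167, tolerance = 2e-4)
  li <- run_scf(mol_system("Li", matrix(0, 1, 3), charge = 1L))
  expect_equal(li$energy, -7.135448, tolerance = 1e-6)
})

test_that("density matrices are normalised, symmetric and idempotent", {
  wt <- qmmeda:::water_template()
  w <- mol_system(wt$element, wt$xyz)
  st <- run_scf(w)
  S <- st$frame$S
  expect_equal(sum(st$D * S), 10, tolerance = 1e-8)      # Tr(D S) = n_elec
  expect_equal(st$D, t(st$D), tolerance = 1e-10)
  # closed-shell idempotency D S D = 2 D
  expect_equal(st$D %*% S %*% st$D, 2 * st$D, tolerance = 1e-7)
})

test_that("one-electron integrals agree with numerical quadrature", {
  # overlap and kinetic elements for a two-center s/p pair, integrated on a
  # dense grid -- an independent route through the same quantities
  sys <- mol_system(c("H", "O", "H"),
                    rbind(c(0.7, 0.1, -0.2), qmmeda:::water_template()$xyz[1:2, ]))
  fr <- qm_frame(sys)
  # numerical overlap of AO 1 (H s) with AO 3 (O 2s) and AO 4 (O 2px)
  grid <- expand.grid(x = seq(-6, 6, length.out = 61),
                      y = seq(-6, 6, length.out = 61),
                      z = seq(-6, 6, length.out = 61))
  h <- (12 / 60)^3
  ao_val <- function(shell, comp, pts) {
    d <- sweep(pts, 2, shell$center)
    r2 <- rowSums(d^2)
    rad <- sapply(seq_along(shell$exps), function(k)
      shell$coefs[k] * exp(-shell$exps[k] * r2))
    rad <- rowSums(rad)
    if (shell$l == 0) rad else rad * d[, comp]
  }
  pts <- as.matrix(grid)
  sh <- fr$shells
  v1 <- ao_val(sh[[1]], 0, pts)          # H 1s
  v3 <- ao_val(sh[[3]], 0, pts)          # O 2s
  v4 <- ao_val(sh[[4]], 1, pts)          # O 2px
  expect_equal(sum(v1 * v3) * h, fr$S[1, 3], tolerance = 1e-4)
  expect_equal(sum(v1 * v4) * h, fr$S[1, 4], tolerance = 1e-4)
})

test_that("ghost basis functions lower fragment energies variationally", {
  sys <- mol_system(c("He", "He"), rbind(c(0, 0, 0), c(3, 0, 0)))
  fr <- qm_frame(sys)
  with_ghost <- run_scf(frame = fr, real_atoms = 1L, charge = 0L)
  alone <- run_scf(mol_system("He", matrix(0, 1, 3)))
  expect_lte(with_ghost$energy, alone$energy + 1e-12)
  expect_equal(with_ghost$n_electrons, 2L)
  expect_equal(sum(with_ghost$D * fr$S), 2, tolerance = 1e-8)
})

test_that("a distant MM charge shifts the energy by the classical far field", {
  wt <- qmmeda:::water_template()
  w <- mol_system(wt$element, wt$xyz)
  fr <- qm_frame(w)
  free <- run_scf(frame = fr)
  mm <- data.frame(x = 50, y = 0, z = 0, q = 1)
  emb <- run_scf(frame = fr, mm_charges = mm)
  shift <- (emb$energy - free$energy) * eda_constants$hartree_kcal
  # classical charge / frozen-distribution interaction: monopole term is
  # zero (neutral water); dipole term mu_x q / r^2
  mu <- dipole_moment(free)
  # charge-dipole interaction k q (mu . rhat) / r^2, rhat toward the charge
  classical <- 332.0637 * mu[1] / 50^2
  expect_lt(abs(shift - classical), 0.01)   # kcal/mol; quadrupole+ remainder
  expect_lt(abs(shift), 0.2)
})

test_that("frozen state: normalisation, idempotency, non-overlap limit", {
  snap <- he_pair_snapshot(100)
  fr <- qm_frame(snap$qm_system)
  sa <- run_scf(frame = fr, real_atoms = 1L, charge = 0L)
  sb <- run_scf(frame = fr, real_atoms = 2L, charge = 0L)
  Hfull <- fr$T + qmmeda:::nuclear_matrix(fr, 1:2)
  frozen <- build_frozen_state(sa, sb, Hfull, qmmeda:::nn_energy(fr, 1:2))
  expect_equal(sum(frozen$D * fr$S), 4, tolerance = 1e-8)
  expect_equal(frozen$D %*% fr$S %*% frozen$D, 2 * frozen$D, tolerance = 1e-7)
  # at 100 A the frozen energy is the sum of fragment energies
  expect_equal(frozen$energy, sa$energy + sb$energy, tolerance = 0.01 / 627.5)
})

test_that("Loewdin frozen state matches a Gram-Schmidt construction oracle", {
  snap <- he_pair_snapshot(2.5)
  fr <- qm_frame(snap$qm_system)
  sa <- run_scf(frame = fr, real_atoms = 1L, charge = 0L)
  sb <- run_scf(frame = fr, real_atoms = 2L, charge = 0L)
  Hfull <- fr$T + qmmeda:::nuclear_matrix(fr, 1:2)
  cst <- qmmeda:::nn_energy(fr, 1:2)
  frozen <- build_frozen_state(sa, sb, Hfull, cst)
  # oracle: explicit Gram-Schmidt of the concatenated occupied orbitals,
  # then the same determinant-energy evaluation.  The determinant (and so
  # its density and energy) is invariant to which orthogonalisation is used.
  C <- cbind(sa$C_occ, sb$C_occ)
  S <- fr$S
  for (j in seq_len(ncol(C))) {
    v <- C[, j]
    if (j > 1) for (k in seq_len(j - 1)) {
      v <- v - as.numeric(t(C[, k]) %*% S %*% v) * C[, k]
    }
    C[, j] <- v / sqrt(as.numeric(t(v) %*% S %*% v))
  }
  D_gs <- 2 * C %*% t(C)
  e_gs <- qmmeda:::energy_of_density(fr, Hfull, D_gs, cst)
  expect_equal(frozen$energy, e_gs, tolerance = 1e-8)
  expect_equal(frozen$D, D_gs, tolerance = 1e-7)
})

test_that("frozen energy bounds the complex SCF energy from above", {
  snap <- water_dimer_snapshot()
  fr <- qm_frame(snap$qm_system)
  sa <- run_scf(frame = fr, real_atoms = 1:3, charge = 0L)
  sb <- run_scf(frame = fr, real_atoms = 4:6, charge = 0L)
  Hfull <- fr$T + qmmeda:::nuclear_matrix(fr, 1:6)
  frozen <- build_frozen_state(sa, sb, Hfull, qmmeda:::nn_energy(fr, 1:6))
  cx <- run_scf(frame = fr, charge = 0L, D_init = sa$D + sb$D)
  expect_gte(frozen$energy, cx$energy)
})

test_that("fragment relaxation: identity at zero field, variational bound", {
  h2 <- mol_system(c("H", "H"), rbind(c(-0.37, 0, 0), c(0.37, 0, 0)))
  fr <- qm_frame(h2)
  s0 <- run_scf(frame = fr)
  zero <- matrix(0, fr$n, fr$n)
  same <- relax_fragment_in_partner_field(s0, zero)
  expect_equal(same$D, s0$D, tolerance = 1e-7)
  expect_equal(same$energy, s0$energy, tolerance = 1e-9)
  # with a field: relaxed energy below the unperturbed density's energy in
  # the same external potential (variational)
  V <- qmmeda:::potential_matrix(fr, matrix(c(15, 0, 0), 1, 3), 1)
  rel <- relax_fragment_in_partner_field(s0, V)
  e_unrelaxed <- qmmeda:::energy_of_density(fr, s0$Hcore + V, s0$D, s0$const)
  expect_lte(rel$energy, e_unrelaxed + 1e-12)
})

test_that("relaxed density reproduces the backend polarizability", {
  # H2 in the field of a +1 e charge at 20 A: the induced dipole must equal
  # alpha * E with alpha computed from the dipole response itself at a
  # different, weaker field (linear response cross-check)
  h2 <- mol_system(c("H", "H"), rbind(c(-0.3707, 0, 0), c(0.3707, 0, 0)))
  fr <- qm_frame(h2)
  s0 <- run_scf(frame = fr)
  relax_at <- function(q) {
    V <- qmmeda:::potential_matrix(fr, matrix(c(20, 0, 0), 1, 3), q)
    relax_fragment_in_partner_field(s0, V)
  }
  mu1 <- dipole_moment(relax_at(1)) - dipole_moment(s0)
  mu_half <- dipole_moment(relax_at(0.5)) - dipole_moment(s0)
  # linearity of the response
  expect_equal(mu1[1] / mu_half[1], 2, tolerance = 0.02)
  alpha <- mu_half[1] / (-0.5 / 400)            # field of +q at +x is -q/r^2
  E <- -1 / 400
  expect_equal(mu1[1], alpha * E, tolerance = abs(alpha * E) * 0.05)
  expect_gt(alpha, 0)
})

test_that("unsupported methods and open shells are rejected", {
  he <- mol_system("He", matrix(0, 1, 3))
  expect_error(run_scf(he, method = "m062x"), "unsupported method")
  expect_error(run_scf(he, charge = 1L), "open-shell")
  expect_error(basis_spec("cc-pvdz"), "not resolvable")
})
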