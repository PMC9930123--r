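test_that("XYZ parsing, round trip and malformed input", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "one water",
               "O 0.0 0.0 0.0",
               "H 0.9572 0.0 0.0",
               "H -0.2399 0.9266 0.0"), f)
  sys <- read_structure(f, "xyz")
  expect_s3_class(sys, "mol_system")
  expect_identical(sys$element, c("O", "H", "H"))
  expect_equal(sum(sys$Z), 10)
  expect_equal(sys$xyz[2, 1], 0.9572)

  # write-then-read reproduces positions
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(sys, f2, comment = "round trip")
  sys2 <- read_structure(f2)
  expect_equal(sys2$xyz, sys$xyz, tolerance = 1e-10)
  expect_identical(sys2$element, sys$element)

  # declared count mismatch
  writeLines(c("4", "bad", "O 0 0 0", "H 1 0 0"), f)
  expect_error(read_structure(f, "xyz"), "declared 4")
  # unknown element
  writeLines(c("1", "bad", "Xx 0 0 0"), f)
  expect_error(read_structure(f, "xyz"), "unknown element")
})

test_that("PDB coordinate records are read with atom order preserved", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 1L, "O", "HOH", "A", 1L, 0.0, 0.0, 0.0, 1.0, 0.0, "O"),
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 2L, "H1", "HOH", "A", 1L, 0.957, 0.0, 0.0, 1.0, 0.0, "H"),
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 3L, "H2", "HOH", "A", 1L, -0.24, 0.927, 0.0, 1.0, 0.0, "")),
    f)
  sys <- read_structure(f, "pdb")
  expect_identical(sys$element, c("O", "H", "H"))   # last element from name
  expect_equal(sys$xyz[2, 1], 0.957)
})

test_that("fragment partition validates and round-trips 0-based JSON", {
  p <- fragment_partition(1:3, 4:6, 1L, -1L, 6)
  expect_error(fragment_partition(1:3, 3:6, 0L, 0L), "overlap")
  expect_error(fragment_partition(1:3, 4:5, 0L, 0L, 6), "cover")
  f <- withr::local_tempfile(fileext = ".json")
  write_fragments(p, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(j$fragment_a, 0:2)   # 0-based on disk
  p2 <- read_fragments(f)
  expect_identical(p2$fragment_a, p$fragment_a)
  expect_identical(p2$charge_b, -1L)
})

test_that("closest-n partition ranks waters by min atom-COM distance", {
  # solute: one He at origin; three waters at 3, 5, 7 A
  wt <- qmmeda:::water_template()
  place <- function(d) sweep(wt$xyz, 2, -c(d, 0, 0))
  sys <- mol_system(c("He", rep(c("O", "H", "H"), 3)),
                    rbind(c(0, 0, 0), place(5), place(3), place(7)))
  raw <- list(system = sys, n_solute_atoms = 1L, solute_charge = 0L,
              water_q = wt$q, dipoles = NULL, provenance = "manual")
  snap <- partition_closest_n(raw, 2)
  expect_equal(length(snap$partition$fragment_b), 6L)
  # QM waters are those at 3 and 5 A: MM region holds the 7 A water
  expect_equal(nrow(snap$mm_region$charges), 3L)
  expect_true(all(abs(snap$mm_region$charges$x) > 5.5))
  # boundary: n = all waters -> empty MM region
  snap_all <- partition_closest_n(raw, 3)
  expect_equal(nrow(snap_all$mm_region$charges), 0L)
  # range error
  expect_error(partition_closest_n(raw, 4), "only 3 available")
})

test_that("closest-n selection matches a brute-force re-ranking oracle", {
  raw <- generate_synthetic_snapshot("glycine_zwitterion", 200, seed = 42)
  snap <- partition_closest_n(raw, 50)
  # oracle: recompute every water's min atom-COM distance directly
  sys <- raw$system
  ns <- raw$n_solute_atoms
  m <- qmmeda:::element_mass(sys$element[1:ns])
  com <- colSums(sys$xyz[1:ns, ] * m) / sum(m)
  dmin <- sapply(seq_len(200), function(w) {
    i <- ns + 3 * (w - 1) + 1
    min(sqrt(rowSums((sys$xyz[i:(i + 2), ] -
                        matrix(com, 3, 3, byrow = TRUE))^2)))
  })
  qm_max <- max(snap$qm_water_com_dist)
  mm_min <- min(snap$mm_water_com_dist)
  expect_lte(qm_max, mm_min)
  expect_equal(sort(snap$qm_water_com_dist), sort(dmin)[1:50])
  # partition completeness: every water atom is in exactly one region
  expect_equal(length(snap$partition$fragment_b) +
                 nrow(snap$mm_region$charges), 3 * 200)
})

test_that("QM-region radius is nondecreasing in n and translation invariant", {
  raw <- generate_synthetic_snapshot("formate", 30, seed = 5)
  radii <- sapply(c(5, 10, 20, 30), function(n)
    max(partition_closest_n(raw, n)$qm_water_com_dist))
  expect_true(all(diff(radii) >= 0))
  # rigid translation leaves the partition unchanged
  raw2 <- raw
  raw2$system <- mol_system(raw$system$element,
                            sweep(raw$system$xyz, 2, c(-12.3, 4.5, 7.7)),
                            charge = raw$system$charge)
  s1 <- partition_closest_n(raw, 10)
  s2 <- partition_closest_n(raw2, 10)
  expect_identical(s1$partition$fragment_b, s2$partition$fragment_b)
  expect_equal(s1$qm_water_com_dist, s2$qm_water_com_dist, tolerance = 1e-9)
})

test_that("synthetic snapshots are rigid, seeded and reproducible", {
  raw <- generate_synthetic_snapshot("ammonium", 1, seed = 7)
  expect_equal(length(raw$system$element), 5 + 3)
  # rigid water geometry to 1e-6 A
  w <- raw$system$xyz[6:8, ]
  expect_equal(sqrt(sum((w[2, ] - w[1, ])^2)), 0.9572, tolerance = 1e-6)
  expect_equal(sqrt(sum((w[3, ] - w[1, ])^2)), 0.9572, tolerance = 1e-6)
  # determinism contract
  raw2 <- generate_synthetic_snapshot("ammonium", 1, seed = 7)
  expect_identical(raw$system$xyz, raw2$system$xyz)
  # different seed moves the water
  raw3 <- generate_synthetic_snapshot("ammonium", 1, seed = 8)
  expect_false(isTRUE(all.equal(raw$system$xyz, raw3$system$xyz)))
  # global RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_synthetic_snapshot("ammonium", 3, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("induced dipoles satisfy mu = alpha * E against a field oracle", {
  raw <- generate_synthetic_snapshot("formate", 100, seed = 1,
                                     polarizable = TRUE)
  sys <- raw$system
  ns <- raw$n_solute_atoms
  tmpl <- qmmeda:::solute_template("formate")
  wt <- qmmeda:::water_template()
  allq <- c(tmpl$q, rep(wt$q, 100))
  # direct pairwise Coulomb-field summation, written independently
  for (w in c(1, 17, 58, 100)) {
    base <- ns + 3 * (w - 1)
    for (a in 1:3) {
      r0 <- sys$xyz[base + a, ]
      E <- c(0, 0, 0)
      for (i in seq_len(nrow(sys$xyz))) {
        if (i %in% (base + 1:3)) next
        d <- r0 - sys$xyz[i, ]
        E <- E + allq[i] * d / sum(d^2)^1.5
      }
      expect_equal(raw$dipoles[base + a, ], wt$alpha[a] * E,
                   tolerance = 1e-10)
    }
  }
  # hydrogens carry no polarizability, hence no dipole
  expect_true(all(raw$dipoles[ns + c(2, 3), ] == 0))
})

test_that("snapshot bundles round-trip through the directory format", {
  snap <- ammonium_snapshot(n_total = 6, n_qm = 2, seed = 3,
                            polarizable = TRUE)
  dir <- withr::local_tempdir()
  write_snapshot_bundle(snap, dir)
  expect_true(all(file.exists(file.path(dir,
    c("qm.xyz", "fragments.json", "mm_charges.pc", "mm_dipoles.dip")))))
  back <- read_snapshot_bundle(dir)
  expect_equal(back$qm_system$xyz, snap$qm_system$xyz, tolerance = 1e-9)
  expect_equal(back$mm_region$charges$q, snap$mm_region$charges$q)
  # files carry 10 decimals; compare absolutely at that precision
  expect_lt(max(abs(back$mm_region$dipoles$mux - snap$mm_region$dipoles$mux)),
            1e-9)
  expect_identical(back$partition$fragment_a, snap$partition$fragment_a)
})

test_that("closed-shell and water-topology validation errors fire", {
  expect_error(mol_system("H", matrix(0, 1, 3)), "closed-shell")
  wt <- qmmeda:::water_template()
  bad <- wt$xyz; bad[2, ] <- bad[2, ] + c(2, 0, 0)   # broken O-H
  sys <- mol_system(c("He", "O", "H", "H"), rbind(c(0, 0, 0), bad))
  raw <- list(system = sys, n_solute_atoms = 1L, solute_charge = 0L,
              water_q = wt$q, dipoles = NULL)
  expect_error(partition_closest_n(raw, 1), "broken water")
})
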