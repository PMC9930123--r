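#' Molecular system container
#'
#' An ordered set of atoms with a total charge and spin multiplicity.  The
#' EDA operates on closed-shell states, so the electron count
#' (sum of Z minus total charge) must be even whenever `multiplicity == 1`.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of Cartesian coordinates in angstrom.
#' @param charge integer total charge in e.
#' @param multiplicity positive integer spin multiplicity (only 1 supported
#'   downstream).
#' @return object of class `mol_system` with fields `element`, `Z`, `xyz`,
#'   `charge`, `multiplicity`.
#' @export
mol_system <- function(element, xyz, charge = 0L, multiplicity = 1L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(element) < 1L) stop("a system needs at least one atom")
  if (nrow(xyz) != length(element)) {
    stop("element and coordinate counts differ")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  Z <- element_Z(element)
  nelec <- sum(Z) - charge
  if (multiplicity == 1L && nelec %% 2L != 0L) {
    stop("odd electron count (", nelec, ") with multiplicity 1: ",
         "the decomposition requires closed-shell fragments")
  }
  structure(list(element = as.character(element), Z = Z, xyz = xyz,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "mol_system")
}

#' @export
print.mol_system <- function(x, ...) {
  cat(sprintf("<mol_system: %d atoms, charge %+d, %d electrons>\n",
              length(x$element), x$charge, sum(x$Z) - x$charge))
  invisible(x)
}

n_electrons <- function(system) sum(system$Z) - system$charge

#' Read a structure file
#'
#' Supports standard XYZ (count line, comment line, `El x y z` records) and
#' PDB (`ATOM`/`HETATM` coordinate records; the element is taken from
#' columns 77-78 or, failing that, from the atom name).  Atom order is
#' preserved exactly as in the file; coordinates are angstrom.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guesses from the extension.
#' @param charge,multiplicity passed to [mol_system()].
#' @return a [mol_system()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           charge = 0L, multiplicity = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") read_xyz(path, charge, multiplicity)
  else read_pdb(path, charge, multiplicity)
}

read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed XYZ (", path, "): fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ (", path, "): line 1 is not an atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("malformed XYZ (", path, "): declared ", n, " atoms but found ",
         length(body), " coordinate lines (line ", length(body) + 2, ")")
  }
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("malformed XYZ (", path, "): line ", i + 2L, " has fewer than 4 fields")
    }
    el[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("malformed XYZ (", path, "): bad coordinates at line ", i + 2L)
    xyz[i, ] <- v
  }
  mol_system(el, xyz, charge, multiplicity)
}

#' Write a system to an XYZ file
#' @param system a [mol_system()].
#' @param path output path.
#' @param comment the comment line.
#' @export
write_xyz <- function(system, path, comment = "") {
  n <- length(system$element)
  rec <- sprintf("%-2s %18.10f %18.10f %18.10f", system$element,
                 system$xyz[, 1], system$xyz[, 2], system$xyz[, 3])
  writeLines(c(as.character(n), comment, rec), path)
  invisible(path)
}

read_pdb <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0L) stop("malformed PDB (", path, "): no ATOM/HETATM records")
  el <- character(length(rec)); xyz <- matrix(NA_real_, length(rec), 3)
  for (i in seq_along(rec)) {
    l <- rec[i]
    v <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                       substr(l, 47, 54))))
    if (anyNA(v)) stop("malformed PDB (", path, "): bad coordinates in record ", i)
    xyz[i, ] <- v
    e <- trimws(substr(l, 77, 78))
    if (!nzchar(e)) {
      e <- gsub("[0-9]", "", trimws(substr(l, 13, 16)))
      e <- substr(e, 1, 1)
    }
    el[i] <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
  }
  mol_system(el, xyz, charge, multiplicity)
}

#' Fragment partition of a QM system
#'
#' Disjoint solute (A) and solvent (B) atom-index sets covering the whole QM
#' system, with fragment charges that sum to the total charge.  Indices are
#' 1-based in R; the JSON interchange format ([read_fragments()]) is 0-based.
#'
#' @param fragment_a,fragment_b integer atom indices (1-based).
#' @param charge_a,charge_b fragment charges in e.
#' @param n_atoms total atom count of the QM system (for validation).
#' @export
fragment_partition <- function(fragment_a, fragment_b, charge_a, charge_b,
                               n_atoms = NULL) {
  fragment_a <- as.integer(fragment_a); fragment_b <- as.integer(fragment_b)
  if (length(intersect(fragment_a, fragment_b)) > 0L) {
    stop("fragment index sets overlap")
  }
  if (!is.null(n_atoms)) {
    u <- sort(union(fragment_a, fragment_b))
    if (!identical(u, seq_len(n_atoms))) {
      stop("fragment indices do not cover all ", n_atoms, " atoms exactly")
    }
  }
  structure(list(fragment_a = fragment_a, fragment_b = fragment_b,
                 charge_a = as.integer(charge_a),
                 charge_b = as.integer(charge_b)),
            class = "fragment_partition")
}

#' Read / write a fragment-assignment JSON file (0-based indices on disk)
#' @param path file path.
#' @rdname fragment_partition
#' @export
read_fragments <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fragment_partition(j$fragment_a + 1L, j$fragment_b + 1L,
                     j$charge_a, j$charge_b)
}

#' @param partition a `fragment_partition`.
#' @rdname fragment_partition
#' @export
write_fragments <- function(partition, path) {
  jsonlite::write_json(list(fragment_a = partition$fragment_a - 1L,
                            fragment_b = partition$fragment_b - 1L,
                            charge_a = partition$charge_a,
                            charge_b = partition$charge_b),
                       path, auto_unbox = TRUE)
  invisible(path)
}

# ---- water and solute templates -------------------------------------------

# Rigid 3-site water: experimental-style r(OH) = 0.9572 A, HOH = 104.52 deg,
# O at origin; charges are the TIP3P set.
water_template <- function() {
  th <- 104.52 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(0.9572, 0, 0),
               c(0.9572 * cos(th), 0.9572 * sin(th), 0))
  list(element = c("O", "H", "H"), xyz = xyz,
       q = c(-0.834, 0.417, 0.417),
       alpha = c(0.53, 0, 0))   # isotropic polarizability, A^3 (O only)
}

# Solute templates: idealised gas-phase-like geometries with simple integer-sum
# template charge sets used only to polarise synthetic solvent dipoles.
solute_template <- function(name = c("ammonium", "glycine_zwitterion",
                                     "formate")) {
  name <- match.arg(name)
  if (name == "ammonium") {
    d <- 1.021 / sqrt(3)
    xyz <- rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d), c(-d, d, -d),
                 c(-d, -d, d))
    return(list(element = c("N", "H", "H", "H", "H"), xyz = xyz,
                charge = 1L, q = c(-0.40, 0.35, 0.35, 0.35, 0.35)))
  }
  if (name == "formate") {
    # planar HCO2-: C at origin, O's at 1.25 A with OCO = 130 deg, H opposite
    half <- 65 * pi / 180
    xyz <- rbind(c(0, 0, 0),
                 c(1.25 * cos(half), 1.25 * sin(half), 0),
                 c(1.25 * cos(half), -1.25 * sin(half), 0),
                 c(-1.10, 0, 0))
    return(list(element = c("C", "O", "O", "H"), xyz = xyz,
                charge = -1L, q = c(0.60, -0.80, -0.80, 0.0)))
  }
  # glycine zwitterion +H3N-CH2-COO-: approximate heavy-atom frame with
  # tetrahedral N/C hydrogens, planar carboxylate
  xyz <- rbind(
    c(0.000,  0.000,  0.000),   # N
    c(1.480,  0.000,  0.000),   # CA
    c(2.080,  1.400,  0.000),   # C
    c(1.420,  2.430,  0.110),   # O
    c(3.330,  1.470, -0.120),   # O
    c(-0.360, -0.950, -0.190),  # HN
    c(-0.400,  0.620, -0.730),  # HN
    c(-0.380,  0.320,  0.910),  # HN
    c(1.830, -0.540,  0.890),   # HA
    c(1.830, -0.560, -0.870))   # HA
  list(element = c("N", "C", "C", "O", "O", "H", "H", "H", "H", "H"),
       xyz = xyz, charge = 0L,
       q = c(-0.30, -0.10, 0.65, -0.80, -0.80, 0.35, 0.35, 0.35, 0.15, 0.15))
}

#' Center of mass (standard atomic masses)
#' @param system a [mol_system()] or anything with `element` and `xyz`.
#' @return length-3 numeric, angstrom.
#' @export
center_of_mass <- function(system) {
  m <- element_mass(system$element)
  colSums(system$xyz * m) / sum(m)
}

# Validate that atoms n_solute+1 .. end form contiguous O,H,H water triplets.
water_blocks <- function(system, n_solute_atoms) {
  n <- length(system$element)
  nw_atoms <- n - n_solute_atoms
  if (nw_atoms %% 3L != 0L) {
    stop("solvent block is not a whole number of O,H,H triplets")
  }
  nw <- nw_atoms %/% 3L
  for (w in seq_len(nw)) {
    i <- n_solute_atoms + 3L * (w - 1L) + 1L
    if (!identical(system$element[i:(i + 2L)], c("O", "H", "H"))) {
      stop("water ", w, " is not an O,H,H triplet (atoms ", i, "-", i + 2L, ")")
    }
    for (h in 1:2) {
      d <- sqrt(sum((system$xyz[i + h, ] - system$xyz[i, ])^2))
      if (d > 1.3) {
        stop("broken water triplet ", w, ": O-H distance ", round(d, 3),
             " A exceeds 1.3 A")
      }
    }
  }
  nw
}

#' Assign the closest-n waters to the QM region
#'
#' Waters are ranked by the minimum distance from any of their three atoms to
#' the solute center of mass (stable sort: ties keep input order).  The `n`
#' closest become fragment B of the QM system; every remaining water atom
#' becomes an MM point charge (with its induced dipole, when present).
#'
#' @param raw a raw solvated system, as produced by
#'   [generate_synthetic_snapshot()]: list with `system` (solute block then
#'   water triplets), `n_solute_atoms`, `solute_charge`, per-atom water
#'   charges `water_q` (length 3: O,H,H), optional `dipoles` (n x 3 matrix,
#'   e angstrom) and `provenance`.
#' @param n_qm_waters number of waters to treat quantum mechanically.
#' @return a `solvated_snapshot`: list with `qm_system`, `partition`
#'   ([fragment_partition()]), `mm_region` ([mm_region()]) and `provenance`.
#' @export
partition_closest_n <- function(raw, n_qm_waters) {
  sys <- raw$system
  ns <- raw$n_solute_atoms
  nw <- water_blocks(sys, ns)
  n_qm_waters <- as.integer(n_qm_waters)
  if (n_qm_waters > nw) {
    stop("requested ", n_qm_waters, " QM waters but only ", nw, " available")
  }
  com <- center_of_mass(list(element = sys$element[seq_len(ns)],
                             xyz = sys$xyz[seq_len(ns), , drop = FALSE]))
  dmin <- numeric(nw)
  for (w in seq_len(nw)) {
    i <- ns + 3L * (w - 1L) + 1L
    dd <- sqrt(rowSums((sys$xyz[i:(i + 2L), , drop = FALSE] -
                          matrix(com, 3, 3, byrow = TRUE))^2))
    dmin[w] <- min(dd)
  }
  ord <- order(dmin)                      # stable in R: ties keep input order
  qm_w <- sort(ord[seq_len(n_qm_waters)]) # QM waters kept in input order
  mm_w <- sort(if (n_qm_waters < nw) ord[(n_qm_waters + 1L):nw] else integer(0))

  qm_atom_idx <- c(seq_len(ns),
                   unlist(lapply(qm_w, function(w)
                     ns + 3L * (w - 1L) + 1:3)))
  qm_sys <- mol_system(sys$element[qm_atom_idx],
                       sys$xyz[qm_atom_idx, , drop = FALSE],
                       charge = raw$solute_charge)
  part <- fragment_partition(seq_len(ns),
                             seq(ns + 1L, length.out = 3L * n_qm_waters),
                             charge_a = raw$solute_charge, charge_b = 0L,
                             n_atoms = length(qm_atom_idx))
  mm_atom_idx <- unlist(lapply(mm_w, function(w) ns + 3L * (w - 1L) + 1:3))
  if (length(mm_atom_idx) > 0L) {
    ch <- data.frame(x = sys$xyz[mm_atom_idx, 1],
                     y = sys$xyz[mm_atom_idx, 2],
                     z = sys$xyz[mm_atom_idx, 3],
                     q = rep(raw$water_q, times = length(mm_w)))
    dip <- NULL
    if (!is.null(raw$dipoles)) {
      dd <- raw$dipoles[mm_atom_idx, , drop = FALSE]
      dip <- data.frame(x = ch$x, y = ch$y, z = ch$z,
                        mux = dd[, 1], muy = dd[, 2], muz = dd[, 3])
    }
    mm <- mm_region(ch, dip)
  } else {
    mm <- mm_region()
  }
  structure(list(qm_system = qm_sys, partition = part, mm_region = mm,
                 provenance = raw$provenance,
                 qm_water_com_dist = dmin[qm_w],
                 mm_water_com_dist = dmin[mm_w]),
            class = "solvated_snapshot")
}

# Coulomb field (e / A^2) at point r from charges (pos, q), optionally
# excluding a set of rows.
coulomb_field <- function(r, pos, q, exclude = integer(0)) {
  keep <- setdiff(seq_len(nrow(pos)), exclude)
  E <- c(0, 0, 0)
  for (i in keep) {
    d <- r - pos[i, ]
    rr <- sqrt(sum(d^2))
    E <- E + q[i] * d / rr^3
  }
  E
}

#' Generate a synthetic solvated snapshot
#'
#' Emulates an MD snapshot: a rigid solute template surrounded by `n_waters`
#' rigid 3-site waters placed with random orientations on concentric shells
#' around the solute, rejecting placements that approach any placed atom
#' closer than `min_dist`.  Waters carry TIP3P charges; with
#' `polarizable = TRUE` each water atom additionally carries an induced
#' dipole mu_i = alpha_i * E(R_i), where E is the static Coulomb field of the
#' solute template charges and all other waters' fixed charges.
#'
#' Identical inputs (including `seed`) produce identical snapshots; the
#' global RNG state is left untouched.
#'
#' @param solute_template `"ammonium"`, `"glycine_zwitterion"` or `"formate"`.
#' @param n_waters number of waters (>= 1).
#' @param seed integer RNG seed (reproducibility contract).
#' @param first_shell radius of the innermost shell, angstrom.
#' @param shell_spacing spacing between shells, angstrom.
#' @param min_dist minimum allowed intermolecular atom-atom distance, angstrom.
#' @param polarizable also assign induced dipoles to water atoms.
#' @param max_tries placement attempts per water and shell before the shell
#'   radius is advanced.
#' @return a raw solvated system suitable for [partition_closest_n()].
#' @export
generate_synthetic_snapshot <- function(solute_template = c("ammonium",
                                          "glycine_zwitterion", "formate"),
                                        n_waters, seed,
                                        first_shell = 3.0,
                                        shell_spacing = 0.8,
                                        min_dist = 2.0,
                                        polarizable = FALSE,
                                        max_tries = 400L) {
  solute_template <- match.arg(solute_template)
  if (n_waters < 1L) stop("n_waters must be >= 1")
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  sol <- solute_template(solute_template)
  wat <- water_template()
  com <- center_of_mass(sol)
  placed_el <- sol$element
  placed_xyz <- sol$xyz
  shell <- 0L
  waters <- vector("list", n_waters)
  for (w in seq_len(n_waters)) {
    ok <- FALSE
    tries <- 0L
    while (!ok) {
      if (tries >= max_tries) {
        shell <- shell + 1L
        tries <- 0L
        if (shell > 500L) {
          stop("packing failed after bounded rejections; ",
               "increase shell_spacing or reduce n_waters")
        }
      }
      tries <- tries + 1L
      r <- first_shell + shell_spacing * (shell + runif(1))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # orient the water dipole along the local field of the solute template
      # charges (as thermalised MD hydration shells do), with a free azimuth
      # and a random thermal tilt of up to ~40 degrees
      Ef <- coulomb_field(com + r * u, sol$xyz, sol$q)
      R <- orient_water_rotation(wat, Ef)
      wxyz <- wat$xyz %*% t(R)
      wcom <- center_of_mass(list(element = wat$element, xyz = wxyz))
      wxyz <- wxyz - matrix(wcom, 3, 3, byrow = TRUE) +
        matrix(com + r * u, 3, 3, byrow = TRUE)
      dmat <- sqrt(pmax(outer(rowSums(wxyz^2), rowSums(placed_xyz^2), "+") -
                          2 * wxyz %*% t(placed_xyz), 0))
      if (min(dmat) >= min_dist) {
        placed_el <- c(placed_el, wat$element)
        placed_xyz <- rbind(placed_xyz, wxyz)
        waters[[w]] <- wxyz
        ok <- TRUE
      }
    }
  }
  sys <- mol_system(placed_el, placed_xyz, charge = sol$charge)
  dip <- NULL
  if (polarizable) {
    ns <- length(sol$element)
    allq <- c(sol$q, rep(wat$q, n_waters))
    dip <- matrix(0, nrow(placed_xyz), 3)
    for (w in seq_len(n_waters)) {
      base <- ns + 3L * (w - 1L)
      own <- base + 1:3
      for (a in 1:3) {
        if (wat$alpha[a] == 0) next
        E <- coulomb_field(placed_xyz[base + a, ], placed_xyz, allq,
                           exclude = own)
        dip[base + a, ] <- wat$alpha[a] * E
      }
    }
  }
  list(system = sys, n_solute_atoms = length(sol$element),
       solute_charge = sol$charge, water_q = wat$q, dipoles = dip,
       provenance = sprintf("synthetic %s + %d waters (seed %d%s)",
                            solute_template, n_waters, as.integer(seed),
                            if (polarizable) ", polarizable" else ""))
}

# Rotation that takes the template water's dipole axis (its HOH bisector,
# pointing from O toward the hydrogens) onto the direction of the field E,
# composed with a uniform random spin about that axis and a random tilt of
# up to ~40 degrees.  A vanishing field falls back to a uniform rotation.
orient_water_rotation <- function(wat, E) {
  nE <- sqrt(sum(E^2))
  if (nE < 1e-12) return(random_rotation())
  b <- wat$xyz[2, ] + wat$xyz[3, ] - 2 * wat$xyz[1, ]
  b <- b / sqrt(sum(b^2))
  target <- E / nE
  R_align <- rotation_between(b, target)
  spin <- axis_rotation(b, runif(1, 0, 2 * pi))        # free azimuth
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  jitter <- axis_rotation(ax, runif(1, 0, 40 * pi / 180))
  jitter %*% R_align %*% spin
}

# Rodrigues rotation about a unit axis.
axis_rotation <- function(axis, theta) {
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cthe <- sum(a * b)
  if (s < 1e-12) {
    if (cthe > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(axis_rotation(ax, pi))
  }
  axis_rotation(v / s, atan2(s, cthe))
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

#' Write / read a snapshot bundle directory
#'
#' A bundle holds `qm.xyz`, `fragments.json` (0-based), `mm_charges.pc` and,
#' when dipoles are present, `mm_dipoles.dip`.
#' @param snapshot a `solvated_snapshot`.
#' @param dir target directory (created if missing).
#' @export
write_snapshot_bundle <- function(snapshot, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(snapshot$qm_system, file.path(dir, "qm.xyz"),
            comment = snapshot$provenance)
  write_fragments(snapshot$partition, file.path(dir, "fragments.json"))
  write_point_charges(snapshot$mm_region$charges, file.path(dir, "mm_charges.pc"))
  if (!is.null(snapshot$mm_region$dipoles)) {
    write_dipoles(snapshot$mm_region$dipoles, file.path(dir, "mm_dipoles.dip"))
  }
  invisible(dir)
}

#' @param dir bundle directory.
#' @param charge total charge of the QM system (fragment charges are read
#'   from `fragments.json`; default uses their sum).
#' @rdname write_snapshot_bundle
#' @export
read_snapshot_bundle <- function(dir, charge = NULL) {
  part <- read_fragments(file.path(dir, "fragments.json"))
  if (is.null(charge)) charge <- part$charge_a + part$charge_b
  qm <- read_xyz(file.path(dir, "qm.xyz"), charge = charge)
  ch <- read_point_charges(file.path(dir, "mm_charges.pc"))
  dipf <- file.path(dir, "mm_dipoles.dip")
  dip <- if (file.exists(dipf)) read_dipoles(dipf) else NULL
  structure(list(qm_system = qm, partition = part,
                 mm_region = mm_region(ch, dip),
                 provenance = paste("bundle", dir)),
            class = "solvated_snapshot")
}
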