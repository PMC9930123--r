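#' MM region: fixed point charges and optional induced dipoles
#'
#' The embedding potential seen by the QM region is built from fixed atomic
#' charges (electrostatic embedding) plus, optionally, induced atomic
#' dipoles frozen at their classical values (polarizable embedding).  Each
#' dipole is represented as a pair of opposite charges +/- |mu|/d placed at
#' R +/- (d/2) mu_hat, with a separation `expansion_separation` that must be
#' much shorter than the shortest QM-MM distance (validated when the QM
#' geometry is known: error if d >= 0.1 x that distance).
#'
#' @param charges data.frame with columns `x`, `y`, `z` (angstrom) and `q` (e).
#' @param dipoles optional data.frame with columns `x`, `y`, `z`, `mux`,
#'   `muy`, `muz` (moments in e angstrom).
#' @param expansion_separation charge-pair separation d, angstrom.
#' @return object of class `mm_region`.
#' @export
mm_region <- function(charges = NULL, dipoles = NULL,
                      expansion_separation = 1e-3) {
  if (is.null(charges)) {
    charges <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          q = numeric(0))
  }
  stopifnot(all(c("x", "y", "z", "q") %in% names(charges)))
  if (!all(is.finite(as.matrix(charges)))) stop("non-finite MM charge data")
  if (!is.null(dipoles)) {
    stopifnot(all(c("x", "y", "z", "mux", "muy", "muz") %in% names(dipoles)))
    if (!all(is.finite(as.matrix(dipoles)))) stop("non-finite MM dipole data")
    if (nrow(dipoles) == 0L) dipoles <- NULL
  }
  if (expansion_separation <= 0) stop("expansion_separation must be positive")
  structure(list(charges = charges, dipoles = dipoles,
                 expansion_separation = expansion_separation),
            class = "mm_region")
}

#' @export
print.mm_region <- function(x, ...) {
  cat(sprintf("<mm_region: %d charges, %d dipoles, d = %g A>\n",
              nrow(x$charges),
              if (is.null(x$dipoles)) 0L else nrow(x$dipoles),
              x$expansion_separation))
  invisible(x)
}

n_mm_atoms <- function(region) nrow(region$charges)

#' Expand an induced dipole into a charge pair
#'
#' Replaces a point dipole mu at R by charges +|mu|/d and -|mu|/d at
#' R +/- (d/2) mu_hat.  The reconstructed moment (charge times displacement)
#' equals mu to machine precision; a zero dipole yields two zero charges at
#' the site.
#'
#' @param position length-3 numeric, angstrom.
#' @param moment length-3 numeric, e angstrom.
#' @param separation pair separation d > 0, angstrom.
#' @return list with `plus`, `minus` (each `position`, `charge`) and
#'   `separation`.
#' @export
expand_dipole <- function(position, moment, separation) {
  if (separation <= 0) stop("separation must be positive")
  m <- sqrt(sum(moment^2))
  if (m == 0) {
    return(list(plus = list(position = position, charge = 0),
                minus = list(position = position, charge = 0),
                separation = separation))
  }
  u <- moment / m
  delta <- m / separation
  list(plus = list(position = position + (separation / 2) * u, charge = delta),
       minus = list(position = position - (separation / 2) * u, charge = -delta),
       separation = separation)
}

# All point charges of a region, dipoles expanded into pairs:
# data.frame(x, y, z, q).
expanded_charges <- function(region) {
  ch <- region$charges
  if (!is.null(region$dipoles)) {
    d <- region$dipoles
    for (i in seq_len(nrow(d))) {
      pe <- expand_dipole(as.numeric(d[i, c("x", "y", "z")]),
                          as.numeric(d[i, c("mux", "muy", "muz")]),
                          region$expansion_separation)
      ch <- rbind(ch,
                  data.frame(x = pe$plus$position[1], y = pe$plus$position[2],
                             z = pe$plus$position[3], q = pe$plus$charge),
                  data.frame(x = pe$minus$position[1], y = pe$minus$position[2],
                             z = pe$minus$position[3], q = pe$minus$charge))
    }
  }
  ch
}

#' Electrostatic potential of an MM region
#'
#' Classical potential sum(q_i / |r - R_i|) at each point, in e/angstrom;
#' dipoles contribute through their charge-pair expansions.
#'
#' @param region an [mm_region()].
#' @param points numeric matrix (m x 3) of field points, angstrom.
#' @return numeric vector of length m.
#' @export
evaluate_mm_potential <- function(region, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  ch <- expanded_charges(region)
  if (nrow(ch) == 0L) return(rep(0, nrow(points)))
  out <- numeric(nrow(points))
  pos <- as.matrix(ch[, c("x", "y", "z")])
  for (k in seq_len(nrow(points))) {
    d2 <- rowSums((pos - matrix(points[k, ], nrow(pos), 3, byrow = TRUE))^2)
    if (any(d2 < (1e-8)^2)) {
      stop("evaluation point ", k, " coincides with charge site ",
           which.min(d2))
    }
    out[k] <- sum(ch$q / sqrt(d2))
  }
  out
}

#' Classical nuclei-MM electrostatic energy
#'
#' E = k * sum_I sum_i Z_I q_i / |R_I - R_i| with
#' k = 332.0637 kcal angstrom / (mol e^2).  This is the solute-nuclei / MM
#' term that must be added to the electrostatic component at QM/MM level;
#' dipoles enter through their charge-pair expansions.
#'
#' @param Z numeric vector of nuclear charges.
#' @param positions numeric matrix (n x 3), angstrom.
#' @param region an [mm_region()].
#' @return energy in kcal/mol.
#' @export
nuclei_mm_energy <- function(Z, positions, region) {
  ch <- expanded_charges(region)
  if (nrow(ch) == 0L || length(Z) == 0L) return(0)
  positions <- matrix(as.numeric(positions), ncol = 3)
  pos <- as.matrix(ch[, c("x", "y", "z")])
  e <- 0
  for (i in seq_along(Z)) {
    d <- sqrt(rowSums((pos - matrix(positions[i, ], nrow(pos), 3,
                                    byrow = TRUE))^2))
    if (any(d < 1e-8)) {
      stop("nucleus ", i, " coincides with MM charge site ", which.min(d))
    }
    e <- e + Z[i] * sum(ch$q / d)
  }
  COULOMB_KCAL * e
}

# Validate the charge-pair separation against the QM geometry: d must be
# < 0.1 x the shortest QM-MM distance.
validate_embedding <- function(region, qm_xyz) {
  if (is.null(region$dipoles) || nrow(region$charges) == 0L) return(invisible(TRUE))
  pos <- as.matrix(region$charges[, c("x", "y", "z")])
  dmin <- Inf
  for (i in seq_len(nrow(qm_xyz))) {
    d <- sqrt(rowSums((pos - matrix(qm_xyz[i, ], nrow(pos), 3, byrow = TRUE))^2))
    dmin <- min(dmin, d)
  }
  if (region$expansion_separation >= 0.1 * dmin) {
    stop("expansion_separation (", region$expansion_separation,
         " A) is not small against the shortest QM-MM distance (",
         round(dmin, 3), " A); need d < 0.1 x that distance")
  }
  invisible(TRUE)
}

#' Merged fragment + MM potential specification
#'
#' Describes the one-electron embedding seen by the SCF backend: the solvent
#' fragment's nuclear attraction is merged with the MM potential (fixed
#' charges plus expanded dipole pairs) while the solute fragment's nuclear
#' potential is untouched.  The MM region attaches to fragment B only.
#'
#' @param partition a [fragment_partition()].
#' @param region an [mm_region()].
#' @return object of class `embedding_spec` carrying the expanded MM charge
#'   table (angstrom / e).
#' @export
merged_fragment_potential <- function(partition, region) {
  structure(list(partition = partition, region = region,
                 mm_charges = expanded_charges(region)),
            class = "embedding_spec")
}

#' Read / write MM point-charge and dipole tables
#'
#' `.pc` files hold whitespace-separated `x y z q` per line (angstrom, e);
#' `.dip` files hold `x y z mux muy muz` (moments in e angstrom, or debye
#' with `unit = "debye"`).  Lines starting with `#` are ignored.
#' @param path file path.
#' @return `read_point_charges()`: data.frame `x,y,z,q`;
#'   `read_dipoles()`: data.frame `x,y,z,mux,muy,muz`.
#' @export
read_point_charges <- function(path) {
  tab <- read_numeric_table(path, 4, c("x", "y", "z", "q"))
  tab
}

#' @param charges data.frame as returned by [read_point_charges()].
#' @rdname read_point_charges
#' @export
write_point_charges <- function(charges, path) {
  writeLines(sprintf("%18.10f %18.10f %18.10f %14.8f",
                     charges$x, charges$y, charges$z, charges$q), path)
  invisible(path)
}

#' @param unit `"e_angstrom"` (native) or `"debye"`.
#' @rdname read_point_charges
#' @export
read_dipoles <- function(path, unit = c("e_angstrom", "debye")) {
  unit <- match.arg(unit)
  tab <- read_numeric_table(path, 6, c("x", "y", "z", "mux", "muy", "muz"))
  if (unit == "debye") {
    tab[, 4:6] <- tab[, 4:6] * eda_constants$debye_e_ang
  }
  tab
}

#' @param dipoles data.frame as returned by [read_dipoles()].
#' @rdname read_point_charges
#' @export
write_dipoles <- function(dipoles, path) {
  writeLines(sprintf("%18.10f %18.10f %18.10f %16.10f %16.10f %16.10f",
                     dipoles$x, dipoles$y, dipoles$z,
                     dipoles$mux, dipoles$muy, dipoles$muz), path)
  invisible(path)
}

read_numeric_table <- function(path, ncol_needed, names) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, ncol_needed))
    names(out) <- names
    return(out)
  }
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != ncol_needed || anyNA(v)) {
      stop("malformed record at data line ", i, " of ", path)
    }
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- names
  out
}
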