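# Built-in Gaussian basis data and shell construction for the RHF backend.
#
# The backend ships the minimal STO-3G set (H-F plus Na), which is small
# enough that every EDA fixture runs in seconds while still giving the
# single-determinant states the decomposition algebra operates on.  Exponents
# and contraction coefficients are the standard published STO-3G values;
# first-row 2sp and third-row 3sp shells share exponents between their s and
# p members, with the universal contraction coefficients of the set.

# per element: list of shells, each shell: l, exps, coefs (unnormalised)
STO3G_DATA <- list(
  H = list(
    list(l = 0L,
         exps  = c(3.425250914, 0.6239137298, 0.1688554040),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422))
  ),
  He = list(
    list(l = 0L,
         exps  = c(6.362421394, 1.158922999, 0.3136497915),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422))
  ),
  Li = list(
    list(l = 0L,
         exps  = c(16.11957475, 2.936200663, 0.7946504870),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(0.6362897469, 0.1478600533, 0.0480886784),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(0.6362897469, 0.1478600533, 0.0480886784),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931))
  ),
  C = list(
    list(l = 0L,
         exps  = c(71.61683735, 13.04509632, 3.530512160),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(2.941249355, 0.6834830964, 0.2222899159),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(2.941249355, 0.6834830964, 0.2222899159),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931))
  ),
  N = list(
    list(l = 0L,
         exps  = c(99.10616896, 18.05231239, 4.885660238),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(3.780455879, 0.8784966449, 0.2857143744),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(3.780455879, 0.8784966449, 0.2857143744),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931))
  ),
  O = list(
    list(l = 0L,
         exps  = c(130.7093214, 23.80886605, 6.443608313),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(5.033151319, 1.169596125, 0.3803889600),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(5.033151319, 1.169596125, 0.3803889600),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931))
  ),
  F = list(
    list(l = 0L,
         exps  = c(166.6791340, 30.36081233, 8.216820672),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(6.464803249, 1.502281245, 0.4885884864),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(6.464803249, 1.502281245, 0.4885884864),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931))
  ),
  Na = list(
    list(l = 0L,
         exps  = c(250.7724300, 45.67851117, 12.36238776),
         coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
    list(l = 0L,
         exps  = c(12.04019274, 2.797881859, 0.9099580170),
         coefs = c(-0.09996722919, 0.3995128261, 0.7001154689)),
    list(l = 1L,
         exps  = c(12.04019274, 2.797881859, 0.9099580170),
         coefs = c(0.1559162750, 0.6076837186, 0.3919573931)),
    list(l = 0L,
         exps  = c(1.478740622, 0.4125648801, 0.1614750979),
         coefs = c(-0.2196203690, 0.2255954336, 0.9003984260)),
    list(l = 1L,
         exps  = c(1.478740622, 0.4125648801, 0.1614750979),
         coefs = c(0.01058760429, 0.5951670053, 0.4620010120))
  )
)

#' Basis-set specification
#'
#' @param name basis-set label; the built-in backend resolves `"sto-3g"`.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(name = "sto-3g") {
  name <- tolower(name)
  if (!identical(name, "sto-3g")) {
    stop("basis '", name, "' is not resolvable by the built-in backend; ",
         "available: sto-3g")
  }
  structure(list(name = name), class = "basis_spec")
}

double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# Normalise a shell: primitive norms for a Cartesian power l on one axis,
# then contraction normalisation from the closed-form self-overlap.
normalize_shell <- function(shell) {
  a <- shell$exps
  l <- shell$l
  nprim <- (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(double_factorial(2 * l - 1))
  c_ <- shell$coefs * nprim
  p <- outer(a, a, "+")
  self <- sum(outer(c_, c_) * (pi / p)^1.5 * double_factorial(2 * l - 1) / (2 * p)^l)
  shell$coefs <- c_ / sqrt(self)
  shell
}

# Build the shell list (centers in bohr) for all atoms of a system, ghosts
# included: a ghost atom contributes its basis functions but no nucleus or
# electrons.  Atom order fixes the AO order.
build_shells <- function(system, basis = basis_spec()) {
  stopifnot(inherits(basis, "basis_spec"))
  shells <- list()
  map <- integer(0)  # atom index of each shell
  for (i in seq_along(system$element)) {
    el <- system$element[i]
    bs <- STO3G_DATA[[el]]
    if (is.null(bs)) {
      stop("no basis data for element '", el, "' in ", basis$name)
    }
    for (sh in bs) {
      sh$center <- as.numeric(system$xyz[i, ]) / BOHR_ANG
      shells[[length(shells) + 1L]] <- normalize_shell(sh)
      map <- c(map, i)
    }
  }
  nbf <- vapply(shells, function(s) if (s$l == 0L) 1L else 3L, integer(1))
  list(shells = shells, atom_of_shell = map, nbf = sum(nbf))
}

# AO indices (1-based) belonging to a set of atoms.
ao_indices_of_atoms <- function(shell_info, atom_idx) {
  sizes <- vapply(shell_info$shells, function(s) if (s$l == 0L) 1L else 3L,
                  integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  out <- integer(0)
  for (k in seq_along(shell_info$shells)) {
    if (shell_info$atom_of_shell[k] %in% atom_idx) {
      out <- c(out, seq(starts[k], stops[k]))
    }
  }
  out
}
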