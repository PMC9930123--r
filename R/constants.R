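#' Physical constants and unit conversions
#'
#' Unit policy: user-facing geometry is in angstrom and elementary charges,
#' all internal electronic-structure math is in atomic units, and energies
#' are reported in kcal/mol.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_kcal}{1 hartree in kcal/mol (627.509474)}
#'   \item{bohr_ang}{1 bohr in angstrom (0.529177210903)}
#'   \item{coulomb_kcal}{Coulomb constant k in kcal mol^-1 angstrom e^-2
#'     (332.0637), used for classical point-charge energies}
#'   \item{debye_e_ang}{1 debye in e angstrom (0.20819434)}
#' }
#' @export
eda_constants <- list(
  hartree_kcal = 627.509474,
  bohr_ang     = 0.529177210903,
  coulomb_kcal = 332.0637,
  debye_e_ang  = 0.20819434
)

HARTREE_KCAL <- eda_constants$hartree_kcal
BOHR_ANG     <- eda_constants$bohr_ang
COULOMB_KCAL <- eda_constants$coulomb_kcal

# Elements the backend's built-in basis covers, with atomic numbers and
# standard atomic masses (u) for center-of-mass work.
ELEMENT_TABLE <- data.frame(
  symbol = c("H", "He", "Li", "C", "N", "O", "F", "Na"),
  Z      = c(1L, 2L, 3L, 6L, 7L, 8L, 9L, 11L),
  mass   = c(1.008, 4.0026, 6.94, 12.011, 14.007, 15.999, 18.998, 22.990),
  stringsAsFactors = FALSE
)

element_Z <- function(symbol) {
  i <- match(symbol, ELEMENT_TABLE$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  ELEMENT_TABLE$Z[i]
}

element_mass <- function(symbol) {
  ELEMENT_TABLE$mass[match(symbol, ELEMENT_TABLE$symbol)]
}
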