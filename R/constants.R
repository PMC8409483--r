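# Physical constants (CODATA 2018) and unit conversions.
# Package units: length A, energy kcal/mol, mass amu, time fs, temperature K.

#' Physical constants used throughout the package
#'
#' A named list of CODATA 2018 constants and the unit conversions implied by
#' the package's working units (angstrom, kcal/mol, amu, fs, K).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{R_kcal}{gas constant, kcal/mol/K}
#'   \item{kB_J}{Boltzmann constant, J/K}
#'   \item{h_J}{Planck constant, J s}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{accel_unit}{converts kcal/mol/A/amu to A/fs^2}
#'   \item{hessian_unit}{converts kcal/mol/A^2/amu to s^-2}
#' }
#' @export
CONST <- list(
  R_kcal = 1.987204259e-3,
  kB_J   = 1.380649e-23,
  h_J    = 6.62607015e-34,
  c_cm   = 2.99792458e10,
  N_A    = 6.02214076e23,
  amu_kg = 1.66053906660e-27,
  kcal_J = 4184,
  # F[kcal/mol/A] / m[amu] * accel_unit = a[A/fs^2]
  accel_unit   = 4184 / 6.02214076e23 / 1.66053906660e-27 * 1e-10,
  # H[kcal/mol/A^2/amu] * hessian_unit = omega^2 [s^-2]
  hessian_unit = 4184 / 6.02214076e23 / 1.66053906660e-27 / 1e-20
)

# standard atomic masses, amu
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904, P = 30.974
)

#' Atomic masses for a vector of element symbols
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(elements) {
  m <- .ATOMIC_MASSES[elements]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Thermal energy k_B T in kcal/mol
#'
#' @param T temperature in K.
#' @return k_B T in kcal/mol.
#' @export
kBT <- function(T = 300) {
  stopifnot(is.finite(T), T > 0)
  CONST$R_kcal * T
}
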