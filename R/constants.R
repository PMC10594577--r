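#' Physical constants used throughout fepkin
#'
#' All energies are kcal mol^-1, lengths Angstrom, masses amu, times seconds,
#' temperatures kelvin, charges elementary charges.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 1.987204e-3 kcal mol^-1 K^-1 (equals the
#'     molar gas constant R in these units).}
#'   \item{R}{Molar gas constant, identical to \code{kB} in kcal mol^-1 K^-1.}
#'   \item{kB_over_h}{k_B/h, 2.0836619e10 K^-1 s^-1, so that the Eyring
#'     prefactor k_B*T/h is 6.2093e12 s^-1 at 298 K.}
#'   \item{f_elec}{Electrostatic conversion factor, 332.0636
#'     kcal Angstrom mol^-1 e^-2.}
#'   \item{kJ_per_kcal}{4.184 kJ per kcal, used to convert the gradient
#'     convergence criterion.}
#' }
#' @export
fepkin_constants <- list(
  kB          = 1.987204e-3,
  R           = 1.987204e-3,
  kB_over_h   = 2.0836619e10,
  f_elec      = 332.0636,
  kJ_per_kcal = 4.184
)

# 1.2 kJ mol^-1 A^-1 expressed in kcal mol^-1 A^-1; the default convergence
# threshold for stationary-point searches.
default_gradient_threshold <- function() 1.2 / fepkin_constants$kJ_per_kcal
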