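# Internal unit system: length Angstrom, energy kcal/mol, mass amu, charge e.
# Time is fs inside the integrator, ps at user-facing interfaces.

#' Physical constants used by the package
#'
#' A named list of the physical constants the package relies on, in the
#' internal unit system (Angstrom, kcal/mol, amu, elementary charge e, fs).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb prefactor, kcal Angstrom mol^-1 e^-2.}
#'   \item{c_cm_fs}{Speed of light, cm fs^-1.}
#'   \item{acc}{Conversion from (kcal mol^-1 A^-1)/amu to A fs^-2.}
#'   \item{eV_kcal}{kcal/mol per electron-volt (e times 1 V).}
#' }
#' @export
fp_constants <- list(
  kB       = 0.0019872042586,
  coulomb  = 332.0637,
  c_cm_fs  = 2.99792458e-5,
  acc      = 4.184e-4,
  eV_kcal  = 23.060548
)

# atomic masses (amu)
.fp_masses <- c(C = 12.011, N = 14.007, O = 15.999, H = 1.008)
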