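#' Physical constants and unit conversions
#'
#' Single registry for the physical constants used throughout the package,
#' together with the conversion factors between the internal unit system
#' (lengths in angstrom, times in ns, diffusion coefficients in
#' \eqn{\mathrm{\AA^2/ns}}, viscosities in mPa s, temperatures in K) and SI.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{kB}{Boltzmann constant, J/K.}
#'     \item{N_A}{Avogadro constant, 1/mol.}
#'     \item{e_charge}{Elementary charge, C.}
#'     \item{eps0}{Vacuum permittivity, C^2/(J m).}
#'     \item{A_per_m}{Angstrom per metre (1e10).}
#'     \item{ns_per_s}{Nanoseconds per second (1e9).}
#'     \item{D_A2ns_per_m2s}{Conversion: 1 m^2/s in A^2/ns units (1e11).}
#'     \item{PaS_per_mPaS}{Pascal seconds per mPa s (1e-3).}
#'   }
#' @examples
#' const <- nsedyn_constants()
#' const$kB * 283.15  # thermal energy at 10 degrees C, in J
#' @export
nsedyn_constants <- function() {
  list(
    kB = 1.380649e-23,
    N_A = 6.02214076e23,
    e_charge = 1.602176634e-19,
    eps0 = 8.8541878128e-12,
    A_per_m = 1e10,
    ns_per_s = 1e9,
    D_A2ns_per_m2s = 1e11,
    PaS_per_mPaS = 1e-3
  )
}

## thermal energy over viscosity, in A^3/ns, for eta in mPa s
.kbt_over_eta_A3ns <- function(eta_mpas, temperature) {
  const <- nsedyn_constants()
  (const$kB * temperature / (eta_mpas * const$PaS_per_mPaS)) *
    1e30 / const$ns_per_s
}

## Bjerrum length in angstrom for a medium of given relative permittivity
.bjerrum_length <- function(temperature, dielectric) {
  const <- nsedyn_constants()
  lb_m <- const$e_charge^2 /
    (4 * pi * const$eps0 * dielectric * const$kB * temperature)
  lb_m * const$A_per_m
}
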