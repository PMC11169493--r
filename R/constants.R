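# Unit system: lengths in Angstrom, energies in cm^-1, times in ps,
# charges in units of the elementary charge e, dipoles in Debye.

#' Physical constants for EET rate calculations
#'
#' Bundles the constants that fix the cm^-1 / Angstrom / ps unit system used
#' throughout the package: the reduced Planck constant in cm^-1 ps, the
#' Boltzmann constant in cm^-1 K^-1, and the temperature used for thermal
#' (Boltzmann) weighting of exciton states.
#'
#' @param hbar Reduced Planck constant, cm^-1 ps.
#' @param kB Boltzmann constant, cm^-1 K^-1.
#' @param temperature Temperature, K.
#' @return An object of class `eet_constants`.
#' @examples
#' eet_constants()
#' eet_constants(temperature = 77)
#' @export
eet_constants <- function(hbar = 5.3088, kB = 0.69504, temperature = 300) {
  stopifnot(is.numeric(hbar), hbar > 0,
            is.numeric(kB), kB > 0,
            is.numeric(temperature), temperature > 0)
  structure(list(hbar = hbar, kB = kB, temperature = temperature),
            class = "eet_constants")
}

# Coulomb constant e^2/(4 pi eps0) in cm^-1 Angstrom e^-2:
# 14.3996 eV*Angstrom x 8065.544 cm^-1/eV
.COULOMB_CM1_ANG <- 14.3996 * 8065.544

# 1 e*Angstrom in Debye
.EA_TO_DEBYE <- 4.803204

# Dipole-dipole constant in cm^-1 D^-2 Angstrom^3
.DIPOLE_CM1 <- .COULOMB_CM1_ANG / .EA_TO_DEBYE^2

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' @export
print.eet_constants <- function(x, ...) {
  cat("EET constants: hbar =", x$hbar, "cm^-1 ps, kB =", x$kB,
      "cm^-1 K^-1, T =", x$temperature, "K\n")
  invisible(x)
}
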