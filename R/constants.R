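# Physical constants (CODATA 2018) and unit conversions.
#
# Internal unit system follows the MD convention: energy kJ/mol, length nm,
# mass amu, time ps, temperature K.  In these units kJ/mol == amu nm^2/ps^2,
# so a mass-weighted Hessian in kJ/mol/(amu nm^2) has eigenvalues in ps^-2.
# Frequencies cross the API in cm^-1 (wavenumbers).

.kB_SI <- 1.380649e-23          # J/K
.h_SI  <- 6.62607015e-34        # J s
.NA    <- 6.02214076e23         # 1/mol
.c_SI  <- 2.99792458e8          # m/s
.c_cm  <- 2.99792458e10         # cm/s
.amu   <- 1.66053906660e-27     # kg

.R_J  <- .kB_SI * .NA           # 8.3144626... J/(mol K)
.kB_kJ <- .R_J / 1000           # kJ/(mol K), molar Boltzmann constant

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 constants the package computes with, mostly for
#' documentation and cross-checking purposes.
#'
#' @return Named list: `kB` (J/K), `h` (J s), `NA_` (1/mol), `c` (m/s),
#'   `R` (J/(mol K)), `amu` (kg).
#' @export
qge_constants <- function() {
  list(kB = .kB_SI, h = .h_SI, NA_ = .NA, c = .c_SI, R = .R_J, amu = .amu)
}

# wavenumber (cm^-1) -> frequency nu (s^-1)
wavenumber_to_hz <- function(wn) wn * .c_cm

# molar photon energy h*nu for wavenumbers, kJ/mol
hnu_molar <- function(wn) .h_SI * wavenumber_to_hz(wn) * .NA / 1000

# dimensionless x = h nu / (kB T) for wavenumbers
hnu_over_kT <- function(wn, T) .h_SI * wavenumber_to_hz(wn) / (.kB_SI * T)
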