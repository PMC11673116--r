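# Physical constants (CODATA 2018) and the internal unit system.
#
# Internally everything is expressed in angstrom / amu / attojoule:
# stretch force constants in aJ A^-2 (numerically equal to mdyn/A),
# bends in aJ rad^-2, mixed blocks in aJ A^-1 rad^-1.

.codata <- list(
  amu_kg  = 1.66053906660e-27,  # atomic mass constant, kg
  c_cm_s  = 2.99792458e10,      # speed of light, cm/s
  aJ_J    = 1e-18,
  ang_m   = 1e-10
)

#' Conversion factor from GF eigenvalues to wavenumbers
#'
#' Eigenvalues of the GF problem in the aJ/amu/angstrom unit system have
#' dimension aJ A^-2 amu^-1; the harmonic wavenumber is
#' \code{omega = freq_conversion_factor() * sqrt(lambda)} in cm^-1.
#' The factor is assembled from CODATA 2018 constants at call time rather
#' than hard-coded.
#'
#' @return scalar conversion factor (approximately 1302.79)
#' @export
freq_conversion_factor <- function() {
  with(.codata, sqrt(aJ_J / (ang_m^2 * amu_kg)) / (2 * pi * c_cm_s))
}

# Masses of the most abundant isotopes, amu (AME2020 rounded); the set covers
# H through Ar, which spans the molecules exercised here.
.atomic_masses <- c(
  H  = 1.00782503207, D = 2.01410177785, He = 4.00260325415,
  Li = 7.01600455,  Be = 9.0121822,   B  = 11.0093054,
  C  = 12.0,        N  = 14.0030740048, O = 15.9949146196,
  F  = 18.99840322, Ne = 19.9924401754,
  Na = 22.9897692809, Mg = 23.985041699, Al = 26.98153863,
  Si = 27.9769265325, P = 30.97376163,  S  = 31.97207100,
  Cl = 34.96885268,  Ar = 39.9623831225
)

#' Look up atomic masses by element symbol
#'
#' @param symbols character vector of element symbols (e.g. \code{"C"}, \code{"H"})
#' @return numeric vector of isotopic masses in amu
#' @export
atomic_mass <- function(symbols) {
  m <- .atomic_masses[symbols]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
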