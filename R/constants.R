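# Physical constants and element defaults.
#
# Internal unit system: length A, time fs, mass amu, charge e, angle radians
# (degrees at API boundaries).  Energies are reported in kcal/mol; the
# integrator converts forces with KCAL_TO_INTERNAL (amu A^2 fs^-2 per kcal/mol).

KCAL_TO_INTERNAL <- 4.184e-4 # 1 kcal/mol in amu A^2 fs^-2 (exact: amu*N_A = 1 g)
KB_KCAL <- 1.987204259e-3 # Boltzmann constant, kcal mol^-1 K^-1
COULOMB_KCAL <- 332.0637128 # e^-2 kcal mol^-1 A
HBAR <- 1.054571817e-34 # J s (CODATA 2018)
MU0_OVER_4PI <- 1e-7 # T^2 m^3 J^-1

# Gyromagnetic ratios (rad s^-1 T^-1, CODATA/IUPAC) of the NMR-active isotope
# conventionally observed for each element; 0 marks elements treated as
# NMR-silent here (16O, 35Cl quadrupolar etc.).
GAMMA_BY_ELEMENT <- c(
  H = 2.6752218744e8, # 1H
  C = 6.728284e7, # 13C
  N = -2.71261804e7, # 15N
  F = 2.51815e8, # 19F
  P = 1.08394e8, # 31P
  O = 0, S = 0, Cl = 0, Br = 0
)

MASS_BY_ELEMENT <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904
)

#' Gyromagnetic ratio of the default NMR-active isotope of an element
#'
#' Returns the gyromagnetic ratio (rad s^-1 T^-1) used in dipolar-coupling
#' back-calculation for atoms of the given element: 1H, 13C, 15N, 19F, 31P are
#' populated; elements without a routinely used spin-1/2 isotope return 0 and
#' are treated as NMR-silent.
#'
#' @param element character vector of element symbols
#' @return numeric vector of gyromagnetic ratios (rad s^-1 T^-1)
#' @export
gyromagnetic_ratio <- function(element) {
  g <- GAMMA_BY_ELEMENT[element]
  g[is.na(g)] <- 0
  unname(g)
}

element_mass <- function(element) {
  m <- MASS_BY_ELEMENT[element]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Decimal half-up rounding for reported percentages
#'
#' Rounds half away from zero on the decimal value (with a tiny tolerance for
#' binary representation), so 19.55 reports as 19.6. Used for the probability
#' percentages in conformer tables and flip aggregates; plain IEEE rounding
#' would send a stored 19.55 to 19.5 because the double sits just below the
#' midpoint.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded values
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
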