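#' Physical constants and unit conversions
#'
#' Internal unit convention: coordinates in angstrom (A), energies in
#' kcal/mol, angles in radians, temperature in kelvin. Force constants are
#' accepted in the units MD packages print (kJ/mol/nm^2 for distances,
#' kJ/mol/rad^2 for angles) and converted on input.
#'
#' @format `KB_KCAL` is the Boltzmann constant in kcal/mol/K.
#' @name constants
NULL

#' @rdname constants
#' @export
KB_KCAL <- 0.0019872041

# kJ/mol -> kcal/mol
KJ_TO_KCAL <- 1 / 4.184

# kJ/mol/nm^2 -> kcal/mol/A^2  (1 nm^2 = 100 A^2)
KJNM2_TO_KCALA2 <- KJ_TO_KCAL / 100

# Avogadro's number, 1/mol
N_AVOGADRO <- 6.02214076e23

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

#' Volume per molecule at a reference concentration
#'
#' At the 1 mol/L standard state one molecule occupies 1660.54 A^3.
#'
#' @param conc_molar concentration in mol/L
#' @return volume in A^3 per molecule
#' @export
standard_volume <- function(conc_molar = 1) {
  stopifnot(conc_molar > 0)
  1e27 / (N_AVOGADRO * conc_molar)
}

#' Convert a distance force constant from kJ/mol/nm^2 to kcal/mol/A^2
#' @param k force constant in kJ/mol/nm^2
#' @return force constant in kcal/mol/A^2
#' @export
k_dist_to_kcal <- function(k) k * KJNM2_TO_KCALA2

#' Convert an angular force constant from kJ/mol/rad^2 to kcal/mol/rad^2
#' @param k force constant in kJ/mol/rad^2
#' @return force constant in kcal/mol/rad^2
#' @export
k_ang_to_kcal <- function(k) k * KJ_TO_KCAL
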