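# Unit conversions and physical constants. All lengths are nm, all volumes nm^3,
# all concentrations molar unless stated otherwise. Every molar <-> number-density
# conversion in the package goes through these two functions.

# molecules per nm^3 in a 1 M solution: N_A / 1e24
.AVOGADRO_NM3 <- 6.02214076e-4

#' Convert a molar concentration to a number density
#'
#' @param c_molar concentration in mol/L.
#' @return number density in molecules per nm^3.
#' @examples
#' molar_to_density(1)      # 6.022e-4 nm^-3
#' molar_to_density(100e-9) # 100 nM
#' @export
molar_to_density <- function(c_molar) {
  stopifnot(is.numeric(c_molar), all(c_molar >= 0))
  c_molar * .AVOGADRO_NM3
}

#' Convert a number density (nm^-3) to a molar concentration
#'
#' @param rho number density in molecules per nm^3.
#' @return concentration in mol/L.
#' @export
density_to_molar <- function(rho) {
  stopifnot(is.numeric(rho), all(rho >= 0))
  rho / .AVOGADRO_NM3
}

#' Volume of a spherical bead
#'
#' @param diameter bead diameter in nm.
#' @return volume in nm^3, (pi/6) d^3.
#' @export
bead_volume <- function(diameter = 0.6) {
  stopifnot(diameter > 0)
  (pi / 6) * diameter^3
}

# Molecular volume of one water molecule (nm^3). The theory needs only a
# consistent solvent site volume; 0.03 nm^3 is the standard choice for
# mean-field molecular theories of aqueous interfaces.
.WATER_VOLUME <- 0.03
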