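#' Physical constants and package units
#'
#' All quantities in the package use GROMACS conventions: lengths in nm,
#' times in ps, energies in kJ/mol, temperatures in K, angles in degrees,
#' masses in g/mol.
#'
#' @format `kB` is the Boltzmann constant in kJ/(mol K).
#' @export
kB <- 0.0083144626

#' @rdname kB
#' @param temperature temperature in K.
#' @return `kBT()` returns the thermal energy k_B * T in kJ/mol.
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB * temperature
}
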