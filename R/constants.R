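# Physical constants used throughout.
#
# All electrostatics in the package are built from the Coulomb constant in
# kcal units; the eV-scale constant is *derived* from it so that the ESTM and
# EPM routes through the same bilinear form agree to machine precision.

# Coulomb constant, kcal * Angstrom / (mol * e^2)
KC_KCAL <- 332.0636

# 1 eV in kcal/mol
EV_TO_KCAL <- 23.0605

# Coulomb constant on the eV scale, eV * Angstrom / e^2 (~= 14.39966)
KC_EV <- KC_KCAL / EV_TO_KCAL

# Gas constant, kcal / (mol * K)
R_GAS_KCAL <- 1.98720e-3

# Default temperature for kT-scale potentials, K
DEFAULT_TEMPERATURE <- 298.15

#' Thermal energy kT
#'
#' Thermal energy at temperature `temperature`, in kcal/mol or eV. At the
#' default 298.15 K, `kT` is about 0.5925 kcal/mol (0.02569 eV); `kT/e` is the
#' conventional output unit of Poisson-Boltzmann potential maps.
#'
#' @param temperature Temperature in kelvin.
#' @param unit `"kcal/mol"` or `"eV"`.
#' @return Scalar thermal energy in the requested unit.
#' @export
#' @examples
#' kT()               # ~0.5925 kcal/mol
#' kT(unit = "eV")    # ~0.02569 eV
kT <- function(temperature = DEFAULT_TEMPERATURE, unit = c("kcal/mol", "eV")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(temperature), temperature > 0)
  kt <- R_GAS_KCAL * temperature
  if (unit == "eV") kt / EV_TO_KCAL else kt
}

#' Convert energies between eV, kcal/mol and kT
#'
#' Conversion uses 1 eV = 23.0605 kcal/mol and kT(T) = R T kcal/mol. Round
#' trips are exact to 1e-12. The `kT` unit is temperature dependent; the
#' default is 298.15 K.
#'
#' @param value Numeric vector of energies.
#' @param from,to One of `"eV"`, `"kcal/mol"`, `"kT"`.
#' @param temperature Temperature in kelvin, used only when `from` or `to`
#'   is `"kT"`.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' convert_energy(0.02, "eV", "kcal/mol")  # ~0.46
#' convert_energy(1, "eV", "kcal/mol")     # 23.0605
convert_energy <- function(value, from, to, temperature = DEFAULT_TEMPERATURE) {
  units <- c("eV", "kcal/mol", "kT")
  if (!is.character(from) || length(from) != 1L || !(from %in% units)) {
    stop("Unknown energy unit '", paste(from, collapse = ","),
         "'; known units: ", paste(units, collapse = ", "), call. = FALSE)
  }
  if (!is.character(to) || length(to) != 1L || !(to %in% units)) {
    stop("Unknown energy unit '", paste(to, collapse = ","),
         "'; known units: ", paste(units, collapse = ", "), call. = FALSE)
  }
  # hub unit: kcal/mol
  in_kcal <- switch(from,
    "eV"       = value * EV_TO_KCAL,
    "kcal/mol" = value,
    "kT"       = value * kT(temperature)
  )
  switch(to,
    "eV"       = in_kcal / EV_TO_KCAL,
    "kcal/mol" = in_kcal,
    "kT"       = in_kcal / kT(temperature)
  )
}
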