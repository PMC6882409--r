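# Dissolved-oxygen unit conversions for freshwater respirometry.
#
# Conventions used throughout the package: temperature in degrees Celsius,
# pressures in kPa, dissolved-oxygen concentration in mg O2 per litre,
# salinity in practical salinity units (default 0, freshwater).

# mole fraction of O2 in dry air
.O2_MOLE_FRACTION <- 0.20946

#' Water conditions for oxygen conversions
#'
#' Bundles the physical context (temperature, barometric pressure, salinity)
#' needed to convert dissolved oxygen between concentration, partial
#' pressure and percent air saturation.
#'
#' @param temperature Water temperature in degrees C. Must lie in [0, 40].
#' @param barometric_pressure Barometric pressure in kPa, in [80, 110].
#'   Default 101.325 (standard atmosphere).
#' @param salinity Salinity in practical salinity units, >= 0. Default 0.
#'
#' @return An object of class `water_conditions`.
#' @examples
#' water_conditions(20)
#' water_conditions(28, barometric_pressure = 100.2)
#' @export
water_conditions <- function(temperature, barometric_pressure = 101.325,
                             salinity = 0) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature < 0 || temperature > 40) {
    stop("`temperature` must be a single value in [0, 40] degrees C",
         call. = FALSE)
  }
  if (!is.numeric(barometric_pressure) || length(barometric_pressure) != 1L ||
      is.na(barometric_pressure) ||
      barometric_pressure < 80 || barometric_pressure > 110) {
    stop("`barometric_pressure` must be a single value in [80, 110] kPa",
         call. = FALSE)
  }
  if (!is.numeric(salinity) || length(salinity) != 1L || is.na(salinity) ||
      salinity < 0) {
    stop("`salinity` must be a single non-negative value", call. = FALSE)
  }
  structure(
    list(temperature = temperature,
         barometric_pressure = barometric_pressure,
         salinity = salinity),
    class = "water_conditions"
  )
}

#' @export
print.water_conditions <- function(x, ...) {
  cat(sprintf("Water conditions: %.1f degC, %.2f kPa, salinity %.1f\n",
              x$temperature, x$barometric_pressure, x$salinity))
  invisible(x)
}

# Saturated water-vapour pressure (kPa) at temperature t (deg C),
# Benson & Krause formulation (T in kelvin, pressure in atm).
vapour_pressure_kpa <- function(temperature) {
  TK <- temperature + 273.15
  u_atm <- exp(11.8571 - 3840.70 / TK - 216961 / TK^2)
  u_atm * 101.325
}

#' Oxygen solubility (air-saturation concentration) of freshwater
#'
#' Equilibrium dissolved-oxygen concentration of water in contact with
#' water-saturated air, after Benson & Krause (1984) as used in the USGS
#' DOTABLES tables, with salinity and barometric-pressure corrections.
#'
#' @param cond A [water_conditions()] object.
#' @return Saturation concentration in mg O2 per litre.
#' @examples
#' o2_saturation_conc(water_conditions(20))  # ~9.09 mg/L
#' @export
o2_saturation_conc <- function(cond) {
  stopifnot(inherits(cond, "water_conditions"))
  t <- cond$temperature
  TK <- t + 273.15
  # baseline solubility at 1 atm moist air
  c_star <- exp(-139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
                  1.243800e10 / TK^3 - 8.621949e11 / TK^4)
  # salinity correction (linear in S on the log scale)
  f_s <- exp(-cond$salinity * (0.017674 - 10.754 / TK + 2140.7 / TK^2))
  # pressure correction
  P_atm <- cond$barometric_pressure / 101.325
  u_atm <- vapour_pressure_kpa(t) / 101.325
  theta <- 0.000975 - 1.426e-5 * t + 6.436e-8 * t^2
  f_p <- P_atm * (1 - u_atm / P_atm) * (1 - theta * P_atm) /
    ((1 - u_atm) * (1 - theta))
  c_star * f_s * f_p
}

# Partial pressure of O2 in water-saturated air at the given conditions (kPa).
po2_air_kpa <- function(cond) {
  stopifnot(inherits(cond, "water_conditions"))
  .O2_MOLE_FRACTION * (cond$barometric_pressure -
                         vapour_pressure_kpa(cond$temperature))
}

#' Convert dissolved oxygen from mg/L to kPa partial pressure
#'
#' A concentration at full air saturation maps, by construction, exactly to
#' the partial pressure of oxygen in water-saturated air at the same
#' conditions.
#'
#' @param conc Dissolved oxygen in mg O2 per litre (vectorised, >= 0).
#' @param cond A [water_conditions()] object.
#' @return Oxygen partial pressure in kPa.
#' @examples
#' o2_mgl_to_kpa(3.5, water_conditions(24))
#' @export
o2_mgl_to_kpa <- function(conc, cond) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be finite and non-negative", call. = FALSE)
  }
  conc / o2_saturation_conc(cond) * po2_air_kpa(cond)
}

#' Convert oxygen partial pressure from kPa to mg/L
#'
#' Exact inverse of [o2_mgl_to_kpa()] under identical conditions.
#'
#' @param po2 Oxygen partial pressure in kPa (vectorised, >= 0).
#' @param cond A [water_conditions()] object.
#' @return Dissolved-oxygen concentration in mg O2 per litre.
#' @examples
#' o2_kpa_to_mgl(20.9, water_conditions(20))  # ~9.1 mg/L
#' @export
o2_kpa_to_mgl <- function(po2, cond) {
  if (any(!is.finite(po2)) || any(po2 < 0)) {
    stop("`po2` must be finite and non-negative", call. = FALSE)
  }
  po2 / po2_air_kpa(cond) * o2_saturation_conc(cond)
}

#' Percent air saturation of a dissolved-oxygen concentration
#'
#' @param conc Dissolved oxygen in mg O2 per litre (vectorised, >= 0).
#' @param cond A [water_conditions()] object.
#' @return Percent of the air-saturation concentration (100 = saturated).
#' @examples
#' o2_percent_saturation(4, water_conditions(28))  # ~51 %
#' @export
o2_percent_saturation <- function(conc, cond) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be finite and non-negative", call. = FALSE)
  }
  100 * conc / o2_saturation_conc(cond)
}
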