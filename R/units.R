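# Seawater oxygen solubility and partial-pressure unit conversions.
#
# Optical oxygen probes report % air saturation; chamber bookkeeping needs
# kPa (partial pressure) and umol/L (amount).  The bridge between the two is
# the air-equilibrium state of the water, which depends on temperature,
# salinity and barometric pressure.

#' Water conditions for oxygen unit conversions
#'
#' Bundles the physical state of the respirometry water: temperature,
#' salinity, barometric pressure and the mole fraction of oxygen in dry air.
#' All solubility and partial-pressure conversions in the package take a
#' `water_conditions` object so that the same state is used consistently
#' throughout a trial.
#'
#' @param temperature_C water temperature in degrees Celsius, in [0, 40].
#' @param salinity_psu practical salinity, in [0, 45].
#' @param pressure_kPa barometric pressure in kPa (default 101.325, one
#'   standard atmosphere).
#' @param o2_fraction mole fraction of O2 in dry air (default 0.2095).
#'
#' @return An object of class `water_conditions`.
#' @examples
#' water_conditions(26, 32)
#' @export
water_conditions <- function(temperature_C, salinity_psu,
                             pressure_kPa = 101.325, o2_fraction = 0.2095) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(salinity_psu), length(salinity_psu) == 1L,
            is.numeric(pressure_kPa), length(pressure_kPa) == 1L,
            is.numeric(o2_fraction), length(o2_fraction) == 1L)
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 40)
    stop("temperature_C must be in [0, 40]", call. = FALSE)
  if (!is.finite(salinity_psu) || salinity_psu < 0 || salinity_psu > 45)
    stop("salinity_psu must be in [0, 45]", call. = FALSE)
  if (!is.finite(pressure_kPa) || pressure_kPa <= 0)
    stop("pressure_kPa must be > 0", call. = FALSE)
  if (!is.finite(o2_fraction) || o2_fraction <= 0 || o2_fraction >= 1)
    stop("o2_fraction must be in (0, 1)", call. = FALSE)
  structure(list(temperature_C = temperature_C,
                 salinity_psu = salinity_psu,
                 pressure_kPa = pressure_kPa,
                 o2_fraction = o2_fraction),
            class = "water_conditions")
}

#' @export
print.water_conditions <- function(x, ...) {
  cat(sprintf("water_conditions: %.2f degC, %.2f psu, %.3f kPa, xO2 %.4f\n",
              x$temperature_C, x$salinity_psu, x$pressure_kPa, x$o2_fraction))
  invisible(x)
}

as_water_conditions <- function(x) {
  if (inherits(x, "water_conditions")) return(x)
  stop("expected a water_conditions object", call. = FALSE)
}

#' Saturation water vapour pressure over seawater
#'
#' Empirical fit of the vapour pressure of water over seawater as a function
#' of temperature and salinity (Weiss & Price 1980).
#'
#' @param temperature_C temperature in degrees Celsius.
#' @param salinity_psu practical salinity.
#' @return Vapour pressure in kPa.
#' @export
water_vapour_pressure <- function(temperature_C, salinity_psu) {
  TK <- temperature_C + 273.15
  p_atm <- exp(24.4543 - 67.4509 * (100 / TK) - 4.8489 * log(TK / 100) -
                 0.000544 * salinity_psu)
  p_atm * 101.325
}

#' Oxygen partial pressure of air-saturated water
#'
#' The PO2 of water in equilibrium with moist air:
#' `o2_fraction * (pressure - vapour_pressure(T, S))`.  This is the "100%
#' air saturation" reference the probe scale is anchored to (about 21 kPa
#' at one atmosphere).
#'
#' @param cond a [water_conditions()] object.
#' @return PO2 at saturation, kPa.
#' @examples
#' po2_at_saturation(water_conditions(26, 32))  # ~20.5 kPa
#' @export
po2_at_saturation <- function(cond) {
  cond <- as_water_conditions(cond)
  pv <- water_vapour_pressure(cond$temperature_C, cond$salinity_psu)
  cond$o2_fraction * (cond$pressure_kPa - pv)
}

#' Convert between % air saturation and kPa
#'
#' `percent_sat_to_kpa()` maps probe readings (% air saturation) onto oxygen
#' partial pressure; `kpa_to_percent_sat()` is its exact inverse.
#'
#' @param pct oxygen in % air saturation (>= 0); vectorised.
#' @param kpa oxygen partial pressure in kPa (>= 0); vectorised.
#' @param cond a [water_conditions()] object.
#' @return Numeric vector in the target unit.
#' @export
percent_sat_to_kpa <- function(pct, cond) {
  if (any(!is.finite(pct)) || any(pct < 0))
    stop("percent saturation must be finite and >= 0", call. = FALSE)
  pct / 100 * po2_at_saturation(cond)
}

#' @rdname percent_sat_to_kpa
#' @export
kpa_to_percent_sat <- function(kpa, cond) {
  if (any(!is.finite(kpa)) || any(kpa < 0))
    stop("kPa values must be finite and >= 0", call. = FALSE)
  kpa / po2_at_saturation(cond) * 100
}

# Garcia & Gordon (1992) refit of the Benson & Krause seawater O2
# solubility data, mL(STP)/L coefficient set.  Exposed as a list so an
# alternative fit can be swapped in through the run configuration.
gg_solubility_coefficients <- function() {
  list(A = c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767),
       B = c(-0.00624523, -0.00737614, -0.0103410, -0.00817083),
       C0 = -4.88682e-7,
       molar_volume_L = 22.3916)
}

#' Dissolved oxygen concentration of air-saturated water
#'
#' Air-equilibrium O2 concentration from the Garcia & Gordon (1992) refit of
#' the Benson & Krause solubility data (mL/L coefficient set, converted to
#' umol/L with the O2 molar volume 22.3916 L/mol).  The fit is defined at a
#' total pressure of one standard atmosphere; for other barometric pressures
#' the value is scaled by the ratio of dry-air partial pressures
#' `(P - pv)/(101.325 - pv)`.
#'
#' @param cond a [water_conditions()] object.
#' @param coef optional coefficient list as returned by
#'   `gg_solubility_coefficients()`, to swap in an alternative fit.
#' @return O2 concentration at air saturation, umol/L.
#' @examples
#' o2_saturation_concentration(water_conditions(10, 35))  # ~282 umol/L
#' @export
o2_saturation_concentration <- function(cond, coef = gg_solubility_coefficients()) {
  cond <- as_water_conditions(cond)
  t <- cond$temperature_C
  S <- cond$salinity_psu
  Ts <- log((298.15 - t) / (273.15 + t))
  lnC <- sum(coef$A * Ts^(seq_along(coef$A) - 1)) +
    S * sum(coef$B * Ts^(seq_along(coef$B) - 1)) + coef$C0 * S^2
  ml_per_L <- exp(lnC)
  umol_per_L <- ml_per_L / coef$molar_volume_L * 1000
  pv <- water_vapour_pressure(t, S)
  umol_per_L * (cond$pressure_kPa - pv) / (101.325 - pv)
}

#' Oxygen solubility per unit partial pressure
#'
#' The Henry's-law proportionality `beta` between dissolved O2 concentration
#' and partial pressure, computed as saturation concentration divided by
#' saturation PO2.  Used to turn kPa/h decline slopes into umol O2/h uptake
#' rates: `rate_umol_h = -slope_kPa_h * beta * volume_L`.  Linearity is
#' assumed across the 0-32 kPa working range.
#'
#' @param cond a [water_conditions()] object.
#' @return Solubility in umol L^-1 kPa^-1.
#' @export
solubility_per_kpa <- function(cond) {
  o2_saturation_concentration(cond) / po2_at_saturation(cond)
}
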