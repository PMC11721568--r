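# Gas solubility, Schmidt numbers, transfer velocities and fluxes.
#
# All temperature arguments are in degrees Celsius, salinity on the practical
# scale, wind speed in m s^-1 at 10 m. Gas transfer velocities are in
# m day^-1 throughout.

#' Saturation water-vapour pressure over seawater
#'
#' Weiss & Price (1980) formulation, in atmospheres.
#'
#' @param temperature Water temperature, deg C.
#' @param salinity Practical salinity.
#' @return Vapour pressure, atm.
#' @export
water_vapour_pressure <- function(temperature, salinity) {
  tk <- temperature + 273.15
  exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
        0.000544 * salinity)
}

#' CO2 solubility coefficient K0
#'
#' Weiss (1974) fit, mol kg^-1 atm^-1, as a function of temperature and
#' salinity. Values outside the fit's range (-2 to 40 deg C, salinity 0-45)
#' are extrapolated with a warning.
#'
#' @inheritParams water_vapour_pressure
#' @return K0 in mol kg^-1 atm^-1.
#' @export
co2_solubility_K0 <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40, na.rm = TRUE)) {
    warning("temperature outside -2..40 degC: K0 extrapolated")
  }
  tk <- (temperature + 273.15) / 100
  exp(-60.2409 + 93.4517 / tk + 23.3585 * log(tk) +
        salinity * (0.023517 - 0.023656 * tk + 0.0047036 * tk^2))
}

# fourth-order Schmidt-number fits in t = deg C
.sc_poly <- function(t, a) a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3 + a[5] * t^4
.SC_CO2_SW <- c(2116.8, -136.25, 4.7353, -0.092307, 0.0007555)
.SC_CO2_FW <- c(1923.6, -125.06, 4.3773, -0.085681, 0.00070284)
.SC_RN_SW  <- c(3489.6, -244.56, 8.9713, -0.18022, 0.0015361)

#' Schmidt number for CO2 or radon
#'
#' Fourth-order polynomial fits in temperature for freshwater and seawater
#' (salinity 35), interpolated linearly in salinity. The radon freshwater
#' curve is the seawater fit rescaled by the freshwater/seawater ratio of the
#' CO2 fits (the viscosity effect is gas-independent to first order).
#'
#' @inheritParams water_vapour_pressure
#' @param gas `"CO2"` or `"Rn"`.
#' @return Dimensionless Schmidt number.
#' @export
schmidt_number <- function(temperature, salinity, gas = c("CO2", "Rn")) {
  gas <- match.arg(gas)
  if (any(temperature < -2 | temperature > 40, na.rm = TRUE)) {
    warning("temperature outside -2..40 degC: Schmidt number extrapolated")
  }
  frac <- salinity / 35
  if (gas == "CO2") {
    sw <- .sc_poly(temperature, .SC_CO2_SW)
    fw <- .sc_poly(temperature, .SC_CO2_FW)
  } else {
    sw <- .sc_poly(temperature, .SC_RN_SW)
    fw <- sw * .sc_poly(temperature, .SC_CO2_FW) / .sc_poly(temperature, .SC_CO2_SW)
  }
  fw + frac * (sw - fw)
}

#' Radon air-water partition coefficient (Ostwald solubility)
#'
#' Weigel freshwater temperature fit `0.105 + 0.405 exp(-0.0502 T)` with an
#' exponential salting-out factor `exp(-0.00615 S)` (about a 20 % reduction
#' at salinity 35). Dimensionless (concentration in water / concentration in
#' air at equilibrium).
#'
#' @inheritParams water_vapour_pressure
#' @return Partition coefficient alpha.
#' @export
rn_partition_alpha <- function(temperature, salinity = 0) {
  if (any(temperature < 0 | temperature > 40, na.rm = TRUE)) {
    warning("temperature outside 0..40 degC: radon partition extrapolated")
  }
  (0.105 + 0.405 * exp(-0.0502 * temperature)) * exp(-0.00615 * salinity)
}

#' Convert air-loop radon concentration to in-water concentration
#'
#' The closed air loop of an equilibrator-based radon detector carries the
#' air-phase equilibrium concentration; multiplying by the partition
#' coefficient gives the water-phase concentration in the same units.
#'
#' @param c_loop Radon concentration in the air loop, dpm m^-3.
#' @inheritParams water_vapour_pressure
#' @return Radon concentration in water, dpm m^-3.
#' @export
rn_loop_to_water <- function(c_loop, temperature, salinity = 0) {
  stopifnot(all(c_loop >= 0, na.rm = TRUE))
  c_loop * rn_partition_alpha(temperature, salinity)
}

#' Convert dry CO2 molar fraction to pCO2
#'
#' `pCO2 = xCO2_dry * (P_atm - p_H2O(T, S))`, the standard correction for a
#' dried equilibrator headspace.
#'
#' @param xco2_dry Dry molar fraction of CO2, ppm.
#' @inheritParams water_vapour_pressure
#' @param atm_pressure Total pressure, atm.
#' @param p_h2o Optional override of the vapour pressure (atm); mainly a
#'   test hook (0 disables the correction).
#' @return pCO2 in microatmospheres.
#' @export
dry_xco2_to_pco2 <- function(xco2_dry, temperature, salinity,
                             atm_pressure = 1, p_h2o = NULL) {
  stopifnot(all(xco2_dry >= 0, na.rm = TRUE))
  if (is.null(p_h2o)) p_h2o <- water_vapour_pressure(temperature, salinity)
  if (any(atm_pressure <= p_h2o, na.rm = TRUE)) {
    stop("atmospheric pressure at or below water vapour pressure (nonphysical)")
  }
  xco2_dry * (atm_pressure - p_h2o)
}

#' Wind-based gas transfer velocity
#'
#' `k = 0.31 u^2 (Sc/660)^-0.5` in cm h^-1, converted to m day^-1
#' (factor 0.24). The quadratic wind dependence assumes wind is the dominant
#' driver of near-surface turbulence.
#'
#' @param wind Wind speed at 10 m, m s^-1.
#' @param sc Schmidt number of the gas at in situ temperature and salinity.
#' @return Gas transfer velocity, m day^-1.
#' @export
gas_transfer_velocity <- function(wind, sc) {
  if (any(wind < 0, na.rm = TRUE)) stop("wind speed must be >= 0")
  stopifnot(all(sc > 0, na.rm = TRUE))
  0.31 * wind^2 * (sc / 660)^(-0.5) * K_CMH_TO_MDAY
}

#' Water-air CO2 flux
#'
#' `F = k K0 dpCO2`, with the microatmosphere gradient converted to
#' atmospheres and mol kg^-1 converted to mmol m^-3 through a constant
#' water density. Positive flux is evasion (water to air).
#'
#' @param k Gas transfer velocity for CO2, m day^-1.
#' @param k0 CO2 solubility, mol kg^-1 atm^-1.
#' @param delta_pco2 Water minus air pCO2, microatm.
#' @param density Water density, kg m^-3.
#' @return Flux in mmol m^-2 day^-1.
#' @export
water_air_co2_flux <- function(k, k0, delta_pco2, density = DEFAULT_DENSITY) {
  stopifnot(all(k >= 0, na.rm = TRUE), all(k0 > 0, na.rm = TRUE))
  k * k0 * delta_pco2 * 1e-3 * density
}

#' Atmospheric radon evasion
#'
#' `J_atm = k (C_w - alpha C_air)`; negative values indicate invasion from an
#' atmosphere enriched relative to the water column.
#'
#' @param k_rn Radon gas transfer velocity, m day^-1.
#' @param c_w Radon in water, dpm m^-3.
#' @param c_air Radon in air, dpm m^-3.
#' @param alpha Air-water partition coefficient.
#' @return Areal evasion rate, dpm m^-2 day^-1.
#' @export
radon_evasion <- function(k_rn, c_w, c_air, alpha) {
  stopifnot(all(k_rn >= 0, na.rm = TRUE))
  k_rn * (c_w - alpha * c_air)
}

#' SGD-derived CO2 flux
#'
#' Multiplies an SGD rate by the groundwater end-member CO2 concentration
#' (computed from its pCO2 via the solubility K0 and water density) to give
#' the CO2 load delivered to the water column per unit area.
#'
#' @param sgd_rate SGD rate, m day^-1 (water-column-equivalent discharge per
#'   unit area).
#' @param gw_pco2 Groundwater end-member pCO2, microatm.
#' @inheritParams water_vapour_pressure
#' @param density Water density, kg m^-3.
#' @param k0 Optional explicit solubility (mol kg^-1 atm^-1); computed from
#'   temperature and salinity when omitted.
#' @return A list with `sgd_rate`, `gw_co2_conc` (mmol m^-3) and `flux`
#'   (mmol m^-2 day^-1).
#' @export
sgd_co2_flux <- function(sgd_rate, gw_pco2, temperature = NULL, salinity = NULL,
                         density = DEFAULT_DENSITY, k0 = NULL) {
  stopifnot(is.finite(sgd_rate), all(gw_pco2 > 0))
  if (is.null(k0)) k0 <- co2_solubility_K0(temperature, salinity)
  if (sgd_rate < 0) warning("negative SGD rate: possible recharge interval")
  conc <- k0 * gw_pco2 * 1e-3 * density   # mmol m^-3
  list(sgd_rate = sgd_rate, gw_co2_conc = conc, flux = sgd_rate * conc)
}

#' Per-timestep water-air CO2 flux series
#'
#' Computes k, K0, the water-air pCO2 gradient and the flux at every
#' timestep of a surface series.
#'
#' @param series A surface time-series tibble (see [read_surface_csv()]).
#' @param atm_pco2 Atmospheric pCO2, microatm.
#' @param density Water density, kg m^-3.
#' @return A tibble with columns `timestamp`, `k_co2_m_d`, `K0`,
#'   `delta_pco2_uatm`, `flux_mmol_m2_d`, plus attributes `mean_flux` and
#'   `sd_flux`.
#' @export
gas_flux_series <- function(series, atm_pco2, density = DEFAULT_DENSITY) {
  sc <- schmidt_number(series$temp_c, series$salinity, "CO2")
  k <- gas_transfer_velocity(series$wind_ms, sc)
  k0 <- co2_solubility_K0(series$temp_c, series$salinity)
  delta <- series$pco2_uatm - atm_pco2
  flux <- water_air_co2_flux(k, k0, delta, density)
  out <- tibble::tibble(
    timestamp = series$timestamp,
    k_co2_m_d = k, K0 = k0,
    delta_pco2_uatm = delta,
    flux_mmol_m2_d = flux
  )
  attr(out, "mean_flux") <- mean(flux, na.rm = TRUE)
  attr(out, "sd_flux") <- stats::sd(flux, na.rm = TRUE)
  out
}
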