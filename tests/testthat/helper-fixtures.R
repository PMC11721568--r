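# shared fixture builders (all fixtures are generated in code)

t0_clock <- as.POSIXct("2023-06-01 00:00:00", tz = "UTC")

# uniform surface series from channel vectors (recycled to length n)
make_surface <- function(n, dt_min = 30, start = t0_clock,
                         pco2 = 500, rn = 2, do_sat = 95, salinity = 35,
                         temp = 25, depth = 2, wind = 3) {
  tibble::tibble(
    timestamp = start + seq(0, by = dt_min * 60, length.out = n),
    pco2_uatm = rep_len(pco2, n),
    rn_dpm_l = rep_len(rn, n),
    do_sat_pct = rep_len(do_sat, n),
    salinity = rep_len(salinity, n),
    temp_c = rep_len(temp, n),
    depth_m = rep_len(depth, n),
    wind_ms = rep_len(wind, n)
  )
}

write_surface_fixture <- function(df, path = withr::local_tempfile(
                                    fileext = ".csv", .local_envir = parent.frame())) {
  out <- df
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, na = "")
  path
}

# independent oracle: ln p_H2O(T,S), same published polynomial evaluated
# separately from the package
oracle_ph2o <- function(t, s) {
  tk <- t + 273.15
  exp(24.4543 - 67.4509 * 100 / tk - 4.8489 * log(tk / 100) - 0.000544 * s)
}

oracle_k0 <- function(t, s) {
  tk <- (t + 273.15) / 100
  exp(-60.2409 + 93.4517 / tk + 23.3585 * log(tk) +
        s * (0.023517 - 0.023656 * tk + 0.0047036 * tk^2))
}

oracle_sc_co2_sw <- function(t) {
  2116.8 - 136.25 * t + 4.7353 * t^2 - 0.092307 * t^3 + 0.0007555 * t^4
}

oracle_alpha <- function(t, s) {
  (0.105 + 0.405 * exp(-0.0502 * t)) * exp(-0.00615 * s)
}
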