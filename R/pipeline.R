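# Per-site end-to-end analysis and multi-site ecosystem summaries.

#' Run the full analysis for one site
#'
#' Executes preprocessing, water-air CO2 fluxes, the radon mass balance,
#' driver attribution (correlations, CUSUM, tidal/diel indices) and the
#' end-member mixing diagnostics. Stages whose preconditions fail (e.g. no
#' tidal signal, no end-member file) yield `NULL` components rather than
#' aborting the rest.
#'
#' @param surface Path to the surface CSV or a `surface_ts` tibble.
#' @param endmember Path to the end-member CSV, a `gw_endmember`, or `NULL`.
#' @param meta Path to the metadata YAML/JSON or a `site_metadata`.
#' @param sgd_method `"nonsteady"` (default) or `"tidal_cycle"`.
#' @param mc_draws Monte Carlo draws for the SGD uncertainty (0 disables).
#' @param seed Seed for the Monte Carlo stage.
#' @return A `site_result` list.
#' @export
run_site <- function(surface, endmember = NULL, meta = NULL,
                     sgd_method = c("nonsteady", "tidal_cycle"),
                     mc_draws = 0, seed = 1L) {
  sgd_method <- match.arg(sgd_method)
  if (is.character(meta)) meta <- read_site_metadata(meta)
  series <- if (is.character(surface)) read_surface_csv(surface, meta)
            else surface
  gw <- if (is.character(endmember)) read_endmember_csv(endmember)
        else endmember

  errors <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  atm_pco2 <- if (!is.null(meta)) meta$atm_pco2 else 415
  fluxes <- try_stage("gas_flux", gas_flux_series(series, atm_pco2))

  extremes <- detect_tidal_extremes(series)
  nontidal <- isTRUE(attr(extremes, "nontidal"))

  sgd <- try_stage("radon_mass_balance", {
    rb <- if (!is.null(meta)) meta$radon_budget else NULL
    if (is.null(rb) && !is.null(gw)) {
      rb <- list(rn_gw = endmember_mean(gw, "rn_dpm_l") * 1000)
    }
    if (is.null(rb)) stop("no radon budget terms (metadata or end-member)")
    area <- if (!is.null(meta) && !is.na(meta$area_A)) meta$area_A else 1
    terms <- do.call(radon_budget_terms, c(list(a = area), rb))
    if (sgd_method == "tidal_cycle" && !nontidal) {
      tidal_cycle_integrated_sgd(series, terms, meta, cycles = extremes)
    } else {
      nonsteady_sgd(series, terms, meta)
    }
  })

  sgd_mc <- NULL
  if (!is.null(sgd) && mc_draws >= 100 && !is.null(gw)) {
    rn_gw_sd <- {
      s <- attr(gw, "summary")
      1000 * s$sd[s$field == "rn_dpm_l"]
    }
    if (is.finite(rn_gw_sd) && rn_gw_sd > 0) {
      area <- if (!is.null(meta) && !is.na(meta$area_A)) meta$area_A else 1
      rb <- if (!is.null(meta)) meta$radon_budget else
        list(rn_gw = endmember_mean(gw, "rn_dpm_l") * 1000)
      terms <- do.call(radon_budget_terms, c(list(a = area), rb))
      sgd_mc <- monte_carlo_uncertainty(
        function(tr) nonsteady_sgd(series, tr, meta),
        terms, spreads = list(rn_gw = rn_gw_sd), n = mc_draws, seed = seed)
    }
  }

  sgd_co2 <- NULL
  if (!is.null(sgd) && !is.null(gw)) {
    sgd_co2 <- try_stage("sgd_co2_flux", sgd_co2_flux(
      sgd_rate = sgd$f_gw / (if (!is.null(meta) && !is.na(meta$area_A))
        meta$area_A else 1),
      gw_pco2 = endmember_mean(gw, "pco2_uatm"),
      temperature = mean(series$temp_c, na.rm = TRUE),
      salinity = mean(series$salinity, na.rm = TRUE)))
  }

  correlations <- try_stage("correlations", correlation_summary(series))
  cusum_rn <- try_stage("cusum_rn", {
    cv <- cusum_driver_response(series$rn_dpm_l, series$pco2_uatm)
    list(curve = cv, changepoint = cusum_changepoint(cv))
  })
  cusum_do <- try_stage("cusum_do", {
    cv <- cusum_driver_response(series$do_sat_pct, series$pco2_uatm)
    list(curve = cv, changepoint = cusum_changepoint(cv))
  })
  indices <- if (nontidal) NULL else {
    try_stage("tidal_diel", lapply(
      stats::setNames(nm = c("pco2", "rn", "do_sat", "salinity")),
      function(p) tidal_diel_indices(series, extremes, p)))
  }
  mixing <- if (is.null(gw)) NULL else {
    try_stage("mixing", mixing_analysis(series, gw))
  }

  structure(list(
    site_id = if (!is.null(meta)) meta$site_id else NA_character_,
    ecosystem = if (!is.null(meta)) meta$ecosystem else NA_character_,
    n_obs = nrow(series),
    mean_pco2 = mean(series$pco2_uatm, na.rm = TRUE),
    median_pco2 = stats::median(series$pco2_uatm, na.rm = TRUE),
    mean_rn = mean(series$rn_dpm_l, na.rm = TRUE),
    mean_do = mean(series$do_sat_pct, na.rm = TRUE),
    co2_saturation_pct = 100 * mean(series$pco2_uatm, na.rm = TRUE) / atm_pco2,
    gas_flux = fluxes,
    mean_flux = if (!is.null(fluxes)) attr(fluxes, "mean_flux") else NA_real_,
    sgd = sgd, sgd_mc = sgd_mc, sgd_co2 = sgd_co2,
    correlations = correlations,
    cusum_rn = cusum_rn, cusum_do = cusum_do,
    tidal_diel = indices, nontidal = nontidal,
    mixing = mixing,
    errors = errors,
    provenance = list(package_version =
                        as.character(utils::packageVersion("sgdflux")),
                      seed = seed, sgd_method = sgd_method)
  ), class = "site_result")
}

#' Summarize site results by ecosystem
#'
#' Per-ecosystem mean, sd and median of CO2 saturation, water-air flux, SGD
#' rate and SGD-derived CO2 flux, plus a grand-mean row across all sites.
#'
#' @param results List of `site_result` objects, or a tidy tibble with
#'   columns `site_id`, `ecosystem`, `co2_saturation_pct`,
#'   `water_air_flux`, `sgd_cm_d`, `sgd_co2_flux`.
#' @return A tibble: one row per ecosystem plus a final `all` row.
#' @export
summarize_sites <- function(results) {
  if (length(results) == 0) stop("no site results to summarize")
  tab <- if (inherits(results, "data.frame")) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(lapply(results, function(r) tibble::tibble(
      site_id = r$site_id,
      ecosystem = r$ecosystem,
      co2_saturation_pct = r$co2_saturation_pct,
      water_air_flux = r$mean_flux,
      sgd_cm_d = if (!is.null(r$sgd)) r$sgd$sgd_rate else NA_real_,
      sgd_co2_flux = if (!is.null(r$sgd_co2)) r$sgd_co2$flux else NA_real_
    )))
  }
  if (nrow(tab) == 0) stop("no site results to summarize")
  summ <- function(df, label) {
    num <- c("co2_saturation_pct", "water_air_flux", "sgd_cm_d",
             "sgd_co2_flux")
    out <- tibble::tibble(ecosystem = label, n_sites = nrow(df))
    for (v in num) {
      out[[paste0(v, "_mean")]] <- mean(df[[v]], na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- stats::sd(df[[v]], na.rm = TRUE)
      out[[paste0(v, "_median")]] <- stats::median(df[[v]], na.rm = TRUE)
    }
    out
  }
  per_eco <- dplyr::bind_rows(lapply(split(tab, tab$ecosystem),
                                     function(df) summ(df, df$ecosystem[1])))
  dplyr::bind_rows(per_eco, summ(tab, "all"))
}
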