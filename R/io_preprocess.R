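# Reading, validation, alignment and lag correction of site data.
#
# Timestamps are local clock time (the tidal/diel indices need local noon and
# midnight); they are parsed into POSIXct with tz = "UTC" purely as a carrier
# of the local clock, and the true UTC offset lives in the site metadata.

SURFACE_COLS <- c("timestamp", "pco2_uatm", "rn_dpm_l", "do_sat_pct",
                  "salinity", "temp_c", "depth_m", "wind_ms")
ENDMEMBER_COLS <- c("sample_id", "pco2_uatm", "rn_dpm_l", "do_sat_pct",
                    "salinity", "temp_c")
ECOSYSTEM_TYPES <- c("coral reef", "mangrove", "salt marsh", "canal",
                     "tidal river", "estuary", "tidal flat", "coastal lake",
                     "seagrass meadow")

#' Construct and validate site metadata
#'
#' @param site_id Site identifier.
#' @param ecosystem One of the nine coastal ecosystem types: coral reef,
#'   mangrove, salt marsh, canal, tidal river, estuary, tidal flat, coastal
#'   lake, seagrass meadow.
#' @param latitude,longitude Decimal degrees.
#' @param tidal_range Tidal range, m (>= 0).
#' @param utc_offset Hours.
#' @param atm_pco2 Atmospheric pCO2, microatm; values outside 300-500 need
#'   `allow_atm_pco2_override = TRUE`.
#' @param atm_rn Atmospheric radon, dpm m^-3.
#' @param area_A Wetted area, m^2.
#' @param volume_V Water volume, m^3; derived from area and mean depth when
#'   omitted downstream.
#' @param atm_pressure Atmospheric pressure, atm.
#' @param radon_budget Optional list of radon budget terms (see
#'   [radon_budget_terms()]).
#' @param allow_atm_pco2_override Allow atmospheric pCO2 outside 300-500.
#' @return A `site_metadata` list.
#' @export
site_metadata <- function(site_id, ecosystem, latitude = NA_real_,
                          longitude = NA_real_, tidal_range = 0,
                          utc_offset = 0, atm_pco2 = 415, atm_rn = 0,
                          area_A = NA_real_, volume_V = NA_real_,
                          atm_pressure = 1, radon_budget = NULL,
                          allow_atm_pco2_override = FALSE) {
  if (!ecosystem %in% ECOSYSTEM_TYPES) {
    stop("unknown ecosystem type: ", ecosystem, call. = FALSE)
  }
  if ((atm_pco2 < 300 || atm_pco2 > 500) && !allow_atm_pco2_override) {
    stop("atm_pco2 outside [300, 500] microatm; set allow_atm_pco2_override")
  }
  stopifnot(tidal_range >= 0, atm_pco2 > 0, atm_rn >= 0)
  structure(list(site_id = site_id, ecosystem = ecosystem,
                 latitude = latitude, longitude = longitude,
                 tidal_range = tidal_range, utc_offset = utc_offset,
                 atm_pco2 = atm_pco2, atm_rn = atm_rn,
                 area_A = area_A, volume_V = volume_V,
                 atm_pressure = atm_pressure, radon_budget = radon_budget),
            class = "site_metadata")
}

#' Read site metadata from YAML or JSON
#'
#' Expects the schema version key `spec: 1`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `site_metadata` list.
#' @export
read_site_metadata <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$spec) || raw$spec != 1) {
    stop("site metadata must declare schema version 'spec: 1'")
  }
  raw$spec <- NULL
  do.call(site_metadata, raw)
}

#' Write site metadata to YAML
#'
#' @param meta A `site_metadata` object.
#' @param path Output path.
#' @export
write_site_metadata <- function(meta, path) {
  out <- c(list(spec = 1), unclass(meta))
  out <- out[!vapply(out, function(x) is.null(x) ||
                       (length(x) == 1 && is.na(x)), logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

.parse_clock <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
}

#' Read a surface-water time series CSV
#'
#' The CSV must carry the exact columns `timestamp` (ISO 8601),
#' `pco2_uatm`, `rn_dpm_l`, `do_sat_pct`, `salinity`, `temp_c`, `depth_m`,
#' `wind_ms`; missing values are empty fields. Rows whose timestamp cannot
#' be parsed are dropped with a message; duplicated or non-increasing
#' timestamps are an error.
#'
#' @param path CSV path.
#' @param meta Optional `site_metadata`, attached as an attribute.
#' @return A tibble of class `surface_ts`.
#' @export
read_surface_csv <- function(path, meta = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(SURFACE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("surface CSV missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- suppressWarnings(.parse_clock(df$timestamp))
  bad <- is.na(ts)
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable timestamps dropped")
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    stop("non-monotone timestamps at row(s): ",
         paste(utils::head(which(d <= 0) + 1, 5), collapse = ", "),
         call. = FALSE)
  }
  df$timestamp <- ts
  out <- tibble::as_tibble(df[SURFACE_COLS])
  validate_surface(out)
  class(out) <- c("surface_ts", class(out))
  attr(out, "meta") <- meta
  out
}

validate_surface <- function(series) {
  stopifnot(all(SURFACE_COLS %in% names(series)))
  if (any(series$rn_dpm_l < 0, na.rm = TRUE)) stop("negative radon activity")
  if (any(series$salinity < 0, na.rm = TRUE)) stop("negative salinity")
  if (any(series$depth_m <= 0, na.rm = TRUE)) stop("non-positive depth")
  invisible(series)
}

#' Write a surface-water series back to CSV
#'
#' Round-trips with [read_surface_csv()].
#'
#' @param series A surface series tibble.
#' @param path Output path.
#' @export
write_surface_csv <- function(series, path) {
  out <- as.data.frame(series)[SURFACE_COLS]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read groundwater end-member samples
#'
#' @param path CSV with columns `sample_id`, `pco2_uatm`, `rn_dpm_l`,
#'   `do_sat_pct`, `salinity`, `temp_c`.
#' @return A `gw_endmember` object: tibble of samples plus a `summary`
#'   attribute of per-field means and sds.
#' @export
read_endmember_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(ENDMEMBER_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("end-member CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  gw_endmember(tibble::as_tibble(df))
}

#' Construct a groundwater end-member object
#'
#' @param samples Tibble of discrete samples (columns as in
#'   [read_endmember_csv()]).
#' @return A `gw_endmember` tibble with `summary` and `n` attributes.
#' @export
gw_endmember <- function(samples) {
  stopifnot(nrow(samples) >= 1)
  num <- samples[setdiff(names(samples), "sample_id")]
  summ <- tibble::tibble(
    field = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
    n = vapply(num, function(x) sum(!is.na(x)), integer(1))
  )
  structure(samples, class = c("gw_endmember", class(samples)),
            summary = summ, n = nrow(samples))
}

#' End-member mean of one field
#'
#' @param gw A `gw_endmember` object.
#' @param field Field name, e.g. `"rn_dpm_l"`.
#' @return Arithmetic mean of the discrete samples.
#' @export
endmember_mean <- function(gw, field) {
  s <- attr(gw, "summary")
  unname(s$mean[s$field == field])
}

# median time step of a channel's non-missing samples, minutes
.native_step_min <- function(ts, x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) return(NA_real_)
  stats::median(diff(as.numeric(ts[ok]))) / 60
}

#' Align all channels onto one uniform time grid
#'
#' The grid is anchored at the first timestamp with a radon value and steps
#' by `target_step` minutes. Channels sampled faster than the grid are
#' averaged within each trailing `target_step` bin (matching a detector that
#' integrates over the preceding interval); slower channels are linearly
#' interpolated. Gaps longer than `2 * target_step` are left missing and
#' flagged in the `gap_flags` attribute.
#'
#' @param series Surface series tibble.
#' @param target_step Grid step, minutes (> 0).
#' @return Aligned `surface_ts` tibble.
#' @export
align_series <- function(series, target_step) {
  if (target_step <= 0) stop("target_step must be > 0 minutes")
  t_num <- as.numeric(series$timestamp)
  anchor <- t_num[which(!is.na(series$rn_dpm_l))[1]]
  if (is.na(anchor)) anchor <- t_num[1]
  step_s <- target_step * 60
  grid <- seq(anchor, max(t_num), by = step_s)
  # identity case: already exactly on this grid
  if (length(grid) == length(t_num) && all(abs(t_num - grid) < 1e-6)) {
    return(series)
  }
  out <- tibble::tibble(timestamp = as.POSIXct(grid, tz = "UTC",
                                               origin = "1970-01-01"))
  gap_flags <- list()
  for (col in setdiff(SURFACE_COLS, "timestamp")) {
    x <- series[[col]]
    ok <- !is.na(x)
    if (sum(ok) < 2) { out[[col]] <- NA_real_; next }
    native <- .native_step_min(series$timestamp, x)
    if (!is.na(native) && native < target_step) {
      # trailing-bin average: samples in (g - step, g]
      idx <- findInterval(t_num[ok] - anchor - 1e-9, c(-step_s, grid - anchor))
      v <- tapply(x[ok], factor(idx, levels = seq_along(grid)),
                  mean, na.rm = TRUE)
      v <- as.numeric(v)
      empty <- !is.finite(v)
      v[empty] <- NA_real_
      if (any(empty)) {
        gap_flags[[length(gap_flags) + 1]] <-
          list(channel = col, from = grid[which(empty)[1]],
               to = grid[utils::tail(which(empty), 1)])
      }
      out[[col]] <- v
    } else {
      out[[col]] <- stats::approx(t_num[ok], x[ok], xout = grid,
                                  rule = 1)$y
      # mask interpolation across long gaps
      gaps <- diff(t_num[ok])
      long <- which(gaps > 2 * step_s)
      for (g in long) {
        lo <- t_num[ok][g]; hi <- t_num[ok][g + 1]
        inside <- grid > lo & grid < hi
        out[[col]][inside] <- NA_real_
        gap_flags[[length(gap_flags) + 1]] <-
          list(channel = col, from = lo, to = hi)
      }
    }
  }
  class(out) <- c("surface_ts", class(out))
  attr(out, "meta") <- attr(series, "meta")
  attr(out, "gap_flags") <- gap_flags
  attr(out, "dt_min") <- target_step
  out
}

#' Correct instrument response lags of the gas channels
#'
#' Equilibrator-based measurements reflect water that entered the system one
#' response time earlier; the gas channels are shifted earlier by their lag
#' (default 10 min for CO2, 30 min for radon) and rows that lose a gas value
#' at the series end are dropped so channels stay aligned. Lags are rounded
#' to whole grid steps; a sub-step lag rounds to zero with a warning.
#'
#' @param series Aligned surface series.
#' @param co2_lag,rn_lag Lags, minutes (>= 0).
#' @return Lag-corrected `surface_ts`.
#' @export
lag_correct <- function(series, co2_lag = 10, rn_lag = 30) {
  n <- nrow(series)
  dt_min <- stats::median(diff(as.numeric(series$timestamp))) / 60
  span <- (n - 1) * dt_min
  if (abs(co2_lag) > span || abs(rn_lag) > span) stop("lag exceeds series span")
  s_co2 <- round(co2_lag / dt_min)
  s_rn <- round(rn_lag / dt_min)
  if (abs(s_co2 * dt_min - co2_lag) > 1e-9 ||
      abs(s_rn * dt_min - rn_lag) > 1e-9) {
    warning("lag not a multiple of the grid step; rounded to nearest step")
  }
  if (s_co2 == 0 && s_rn == 0) return(series)
  lo <- 1 + max(0, -s_co2, -s_rn)
  hi <- n - max(0, s_co2, s_rn)
  if (hi <= lo) stop("lag exceeds series span")
  keep <- lo:hi
  out <- series[keep, , drop = FALSE]
  out$pco2_uatm <- series$pco2_uatm[keep + s_co2]
  out$rn_dpm_l <- series$rn_dpm_l[keep + s_rn]
  out
}
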