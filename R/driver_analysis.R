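# Driver attribution: what moves surface-water pCO2?
#
# Pearson correlations against the groundwater tracer (222Rn), the
# metabolism proxy (DO) and salinity; CUSUM driver-response curves with a
# changepoint read-out; tidal extreme detection; peak-hour bracketing; and
# tidal/diel effect indices.

#' Pairwise Pearson correlations of pCO2 against candidate drivers
#'
#' pCO2 is correlated against radon, DO saturation, salinity and depth on
#' pairwise-complete observations. A pair is flagged moderate when
#' `|r| >= 0.5` and significant when the two-sided p-value is below 0.05.
#'
#' @param series Surface series tibble.
#' @return Tibble with columns `pair`, `r`, `p`, `n`, `moderate`,
#'   `significant`, `undefined`.
#' @export
correlation_summary <- function(series) {
  drivers <- c(rn = "rn_dpm_l", do_sat = "do_sat_pct",
               salinity = "salinity", depth = "depth_m")
  rows <- lapply(names(drivers), function(nm) {
    x <- series[[drivers[[nm]]]]
    y <- series$pco2_uatm
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(pair = paste0("pco2_vs_", nm), r = NA_real_,
                            p = NA_real_, n = n, moderate = NA,
                            significant = NA, undefined = TRUE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(pair = paste0("pco2_vs_", nm),
                   r = unname(ct$estimate), p = ct$p.value, n = n,
                   moderate = abs(ct$estimate) >= 0.5,
                   significant = ct$p.value < 0.05, undefined = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' CUSUM driver-response curve
#'
#' The response is standardized (z-scores with the population standard
#' deviation), the pairs are sorted by ascending driver value (stable sort:
#' ties keep time order), and the cumulative sum `s_i = z_i + s_(i-1)` is
#' returned. Slope changes of `s` along the sorted driver reveal the driver
#' value above which the response increases.
#'
#' @param driver Numeric driver series.
#' @param response Numeric response series, paired with `driver`.
#' @return A `cusum_curve` list: `driver_sorted`, `z`, `s`, `flat`.
#' @export
cusum_driver_response <- function(driver, response) {
  ok <- stats::complete.cases(driver, response)
  driver <- driver[ok]; response <- response[ok]
  n <- length(driver)
  if (n < 3) stop("need at least 3 paired observations")
  sd_pop <- sqrt(mean((response - mean(response))^2))
  flat <- sd_pop == 0
  z <- if (flat) rep(0, n) else (response - mean(response)) / sd_pop
  ord <- order(driver)                     # stable: ties keep input order
  z_sorted <- z[ord]
  structure(list(driver_sorted = driver[ord], z = z_sorted,
                 s = cumsum(z_sorted), flat = flat),
            class = "cusum_curve")
}

#' Changepoint of a CUSUM curve
#'
#' Fits a continuous two-segment piecewise-linear model of the cumulative
#' sum against rank and reports the driver value at the breakpoint when the
#' second segment's slope turns upward and the two-segment fit clearly beats
#' a single line. Monotone or flat curves report no changepoint.
#'
#' @param curve A `cusum_curve`.
#' @param min_improvement Minimum fractional SSE reduction over a single
#'   line for a changepoint to be declared.
#' @return The driver value at the breakpoint, or `NA` if none.
#' @export
cusum_changepoint <- function(curve, min_improvement = 0.2) {
  s <- curve$s
  n <- length(s)
  if (n < 10) stop("need at least 10 points for a changepoint fit")
  if (curve$flat) return(NA_real_)
  rank <- seq_len(n)
  sse_lin <- sum(stats::lm.fit(cbind(1, rank), s)$residuals^2)
  # smooth-trend reference: a threshold should produce a kink sharper than
  # any smooth curvature (a uniformly increasing response gives a smooth
  # parabolic CUSUM that a quadratic absorbs entirely)
  sse_quad <- sum(stats::lm.fit(cbind(1, rank, rank^2), s)$residuals^2)
  best <- list(sse = Inf, b = NA_integer_, slopes = c(NA, NA))
  for (b in 2:(n - 1)) {
    x2 <- pmax(rank - b, 0)
    fit <- stats::lm.fit(cbind(1, rank, x2), s)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse) {
      beta <- fit$coefficients
      best <- list(sse = sse, b = b,
                   slopes = c(beta[2], beta[2] + beta[3]))
    }
  }
  improvement <- (sse_lin - best$sse) / sse_lin
  # changepoint only where the slope turns positive and the kink beats the
  # smooth alternative
  if (!is.finite(improvement) || improvement < min_improvement ||
      best$sse >= sse_quad ||
      !(best$slopes[2] > 0 && best$slopes[2] > best$slopes[1])) {
    return(NA_real_)
  }
  curve$driver_sorted[best$b]
}

#' Detect low and high tides from a depth record
#'
#' Local extrema of a lightly smoothed depth series, with alternation of
#' lows and highs enforced and a minimum separation between same-kind
#' extremes (8 h by default, suited to semidiurnal tides). A depth range
#' below 0.05 m classifies the site as nontidal.
#'
#' @param series Surface series tibble (or any tibble with `timestamp` and
#'   `depth_m`).
#' @param min_separation_h Minimum spacing between same-kind extremes, hours.
#' @param smooth_h Smoothing window, hours.
#' @return Tibble with columns `time`, `kind` (`"low"`/`"high"`),
#'   `depth_m`; zero rows with attribute `nontidal = TRUE` for nontidal
#'   records.
#' @export
detect_tidal_extremes <- function(series, min_separation_h = 8,
                                  smooth_h = 1) {
  t <- series$timestamp
  d <- series$depth_m
  ok <- !is.na(d)
  t <- t[ok]; d <- d[ok]
  out_empty <- structure(tibble::tibble(time = t[0], kind = character(0),
                                        depth_m = numeric(0)),
                         nontidal = TRUE)
  if (length(d) < 5 || diff(range(d)) < 0.05) return(out_empty)
  dt_h <- stats::median(diff(as.numeric(t))) / 3600
  win <- max(3, 2 * floor(smooth_h / dt_h / 2) + 1)
  sm <- stats::filter(d, rep(1 / win, win), sides = 2)
  sm[is.na(sm)] <- d[is.na(sm)]
  sm <- as.numeric(sm)
  dd <- diff(sm)
  # sign changes of the first difference
  sgn <- sign(dd); sgn[sgn == 0] <- NA
  sgn <- zoo_locf(sgn)
  turns <- which(diff(sgn) != 0) + 1
  # edge guard: the smoother is unreliable within one window of the ends
  turns <- turns[turns > win & turns <= length(sm) - win]
  if (length(turns) == 0) return(out_empty)
  kind <- ifelse(sgn[turns] > 0, "low", "high")  # sign after turn: rising => was a low
  ext <- tibble::tibble(time = t[turns], kind = kind, depth_m = d[turns])
  # enforce minimum separation between same-kind extremes, keep the extremer
  ext <- ext[order(ext$time), ]
  keep <- rep(TRUE, nrow(ext))
  for (k in c("low", "high")) {
    idx <- which(ext$kind == k & keep)
    i <- 1
    while (i < length(idx)) {
      a <- idx[i]; b <- idx[i + 1]
      if (difftime(ext$time[b], ext$time[a], units = "hours") <
          min_separation_h) {
        drop <- if (k == "low") {
          if (ext$depth_m[a] <= ext$depth_m[b]) b else a
        } else {
          if (ext$depth_m[a] >= ext$depth_m[b]) b else a
        }
        keep[drop] <- FALSE
        idx <- which(ext$kind == k & keep)
      } else i <- i + 1
    }
  }
  ext <- ext[keep, ]
  # enforce alternation: among consecutive same-kind extremes keep the extremer
  repeat {
    same <- which(ext$kind[-1] == ext$kind[-nrow(ext)])
    if (length(same) == 0) break
    i <- same[1]
    drop <- if (ext$kind[i] == "low") {
      if (ext$depth_m[i] <= ext$depth_m[i + 1]) i + 1 else i
    } else {
      if (ext$depth_m[i] >= ext$depth_m[i + 1]) i + 1 else i
    }
    ext <- ext[-drop, ]
  }
  structure(ext, nontidal = FALSE)
}

# last-observation-carried-forward for interior NAs (base implementation)
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  x[idx + (idx == 0)]  # leading NAs take the first value
}

#' Mean of each channel around event peak hours
#'
#' For each event (tidal extreme or diel anchor) the mean of every channel
#' within +/- 1 hour of the event time; empty windows are skipped with a
#' flag.
#'
#' @param series Surface series tibble.
#' @param events Tibble with `time` and `kind` columns.
#' @param window_h Half-window, hours.
#' @return Tibble: one row per event with per-channel means and `n_samples`.
#' @export
peak_hour_means <- function(series, events, window_h = 1) {
  t_num <- as.numeric(series$timestamp)
  chans <- setdiff(SURFACE_COLS, "timestamp")
  rows <- lapply(seq_len(nrow(events)), function(i) {
    t0 <- as.numeric(events$time[i])
    sel <- abs(t_num - t0) <= window_h * 3600
    if (!any(sel)) {
      return(tibble::tibble(time = events$time[i], kind = events$kind[i],
                            n_samples = 0L))
    }
    m <- lapply(chans, function(cl) mean(series[[cl]][sel], na.rm = TRUE))
    names(m) <- chans
    tibble::tibble(time = events$time[i], kind = events$kind[i],
                   n_samples = sum(sel), !!!m)
  })
  dplyr::bind_rows(rows)
}

# diel anchors: every 12:00 (day) and 00:00 (night) local clock in the record
.diel_anchors <- function(timestamps) {
  days <- unique(as.Date(timestamps))
  anchors <- c(as.POSIXct(paste(days, "12:00:00"), tz = "UTC"),
               as.POSIXct(paste(days, "00:00:00"), tz = "UTC"))
  kinds <- rep(c("day", "night"), each = length(days))
  keep <- anchors >= min(timestamps) & anchors <= max(timestamps)
  out <- tibble::tibble(time = anchors[keep], kind = kinds[keep])
  out[order(out$time), ]
}

#' Tidal and diel effect indices
#'
#' For each successive low-high tide pair and day-night (12:00 / 00:00
#' local) pair, the parameter mean over +/- 1 h peak-hour brackets gives
#' `TEI = (eta_H - eta_L) / (2 eta_bar)` and
#' `DEI = (eta_D - eta_N) / (2 eta_bar)`, with `eta_bar` the whole-record
#' parameter mean. Per-cycle indices are averaged arithmetically; the
#' dominance ratio `|TEI| / |DEI|` classifies the site as tidally (> 1) or
#' diurnally (< 1) controlled.
#'
#' @param series Surface series tibble.
#' @param events Tidal extremes from [detect_tidal_extremes()]; detected
#'   internally when `NULL`.
#' @param parameter Channel: `"pco2"`, `"rn"`, `"do_sat"` or `"salinity"`.
#' @return A `tidal_diel_indices` list: `tei`, `dei`, `eta_h`, `eta_l`,
#'   `eta_d`, `eta_n`, `eta_bar`, `dominance`, `tidal_dominated`, plus
#'   per-cycle tibbles.
#' @export
tidal_diel_indices <- function(series, events = NULL,
                               parameter = c("pco2", "rn", "do_sat",
                                             "salinity")) {
  parameter <- match.arg(parameter)
  col <- c(pco2 = "pco2_uatm", rn = "rn_dpm_l", do_sat = "do_sat_pct",
           salinity = "salinity")[[parameter]]
  eta_bar <- mean(series[[col]], na.rm = TRUE)
  if (!is.finite(eta_bar) || eta_bar == 0) {
    stop("whole-record mean of ", parameter, " is zero or undefined")
  }
  if (is.null(events)) events <- detect_tidal_extremes(series)

  # pair successive anchors of opposite kind (either order within the pair)
  pair_cycles <- function(pm, kinds, eta_names, index_fn) {
    rows <- list()
    i <- 1
    while (i < nrow(pm)) {
      if (pm$kind[i] != pm$kind[i + 1]) {
        a <- if (pm$kind[i] == kinds[1]) i else i + 1
        b <- if (pm$kind[i] == kinds[2]) i else i + 1
        row <- tibble::tibble(pm$time[a], pm$time[b],
                              pm[[col]][a], pm[[col]][b],
                              index_fn(pm[[col]][a], pm[[col]][b]))
        names(row) <- c(paste0(kinds, "_time"), eta_names, "index")
        rows[[length(rows) + 1]] <- row
        i <- i + 2
      } else i <- i + 1
    }
    dplyr::bind_rows(rows)
  }

  # tidal cycles: each successive low-high pair
  tei_cycles <- NULL
  if (nrow(events) >= 2) {
    pm <- peak_hour_means(series, events)
    pm <- pm[pm$n_samples > 0, ]
    tei_cycles <- pair_cycles(pm, c("low", "high"), c("eta_l", "eta_h"),
                              function(l, h) (h - l) / (2 * eta_bar))
    if (!is.null(tei_cycles) && nrow(tei_cycles) > 0) {
      names(tei_cycles)[names(tei_cycles) == "index"] <- "tei"
    }
  }

  # diel cycles: each successive day (12:00) / night (00:00) pair
  anchors <- .diel_anchors(series$timestamp)
  pm_d <- peak_hour_means(series, anchors)
  pm_d <- pm_d[pm_d$n_samples > 0, ]
  dei_cycles <- pair_cycles(pm_d, c("day", "night"), c("eta_d", "eta_n"),
                            function(d, n) (d - n) / (2 * eta_bar))
  if (nrow(dei_cycles) > 0) {
    names(dei_cycles)[names(dei_cycles) == "index"] <- "dei"
  }

  tei <- if (!is.null(tei_cycles) && nrow(tei_cycles) > 0) {
    mean(tei_cycles$tei)
  } else NA_real_
  dei <- if (nrow(dei_cycles) > 0) mean(dei_cycles$dei) else NA_real_
  dominance <- if (is.finite(tei) && is.finite(dei) && dei != 0) {
    abs(tei) / abs(dei)
  } else NA_real_
  structure(list(
    parameter = parameter, eta_bar = eta_bar,
    eta_h = if (!is.null(tei_cycles) && nrow(tei_cycles) > 0)
      mean(tei_cycles$eta_h) else NA_real_,
    eta_l = if (!is.null(tei_cycles) && nrow(tei_cycles) > 0)
      mean(tei_cycles$eta_l) else NA_real_,
    eta_d = if (nrow(dei_cycles) > 0) mean(dei_cycles$eta_d) else NA_real_,
    eta_n = if (nrow(dei_cycles) > 0) mean(dei_cycles$eta_n) else NA_real_,
    tei = tei, dei = dei, dominance = dominance,
    tidal_dominated = if (is.finite(dominance)) dominance > 1 else NA,
    tei_cycles = tei_cycles, dei_cycles = dei_cycles
  ), class = "tidal_diel_indices")
}
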