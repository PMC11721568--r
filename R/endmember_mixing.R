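# Two-end-member mixing diagnostics: does conservative mixing between
# surface water and the groundwater end-member explain the observed pCO2?
# The surface pCO2-vs-radon regression is projected to the groundwater
# end-member radon; the deviation from the measured end-member pCO2,
# normalized by it, is the deviation quotient (DQ, %). |DQ| <= 100 is read
# as SGD being the primary driver.

#' OLS regression of surface pCO2 on radon
#'
#' @param series Surface series tibble.
#' @return List with `slope_S` (microatm per dpm L^-1), `intercept_In`
#'   (microatm), `r` and `n`.
#' @export
mixing_regression <- function(series) {
  ok <- stats::complete.cases(series$rn_dpm_l, series$pco2_uatm)
  x <- series$rn_dpm_l[ok]; y <- series$pco2_uatm[ok]
  if (length(x) < 3) stop("need at least 3 paired pCO2/radon observations")
  if (stats::sd(x) == 0) stop("radon has zero variance: regression undefined")
  fit <- stats::lm(y ~ x)
  list(slope_S = unname(coef(fit)[2]), intercept_In = unname(coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}

#' Deviation of the projected end-member from the measured one
#'
#' `D = S * Rn_gw_mean + In - pCO2_gw_mean` (microatm). Positive D means
#' additional CO2 sources beyond mixing; negative D, additional sinks.
#'
#' @param slope_S,intercept_In Regression coefficients from
#'   [mixing_regression()].
#' @param rn_gw_mean End-member radon mean, dpm L^-1.
#' @param pco2_gw_mean End-member pCO2 mean, microatm (> 0).
#' @return D in microatm.
#' @export
deviation <- function(slope_S, intercept_In, rn_gw_mean, pco2_gw_mean) {
  stopifnot(pco2_gw_mean > 0)
  slope_S * rn_gw_mean + intercept_In - pco2_gw_mean
}

#' Deviation quotient
#'
#' `DQ = 100 * D / pCO2_gw_mean`, in percent.
#'
#' @param D Deviation, microatm.
#' @param pco2_gw_mean End-member pCO2 mean, microatm (> 0).
#' @return DQ in percent.
#' @export
deviation_quotient <- function(D, pco2_gw_mean) {
  if (pco2_gw_mean <= 0) stop("pco2_gw_mean must be > 0")
  100 * D / pco2_gw_mean
}

#' Classify the mixing diagnosis from DQ
#'
#' Within the closed band -100 <= DQ <= 100 surface pCO2 tracks the
#' groundwater mixing line and SGD is called the primary driver; above it,
#' other CO2 sources dominate; below it, other sinks.
#'
#' @param DQ Deviation quotient, percent.
#' @return One of `"sgd_primary_driver"`, `"other_sources"`,
#'   `"other_sinks"`.
#' @export
classify_mixing <- function(DQ) {
  stopifnot(is.finite(DQ))
  if (DQ > 100) "other_sources"
  else if (DQ < -100) "other_sinks"
  else "sgd_primary_driver"
}

#' Full mixing analysis of one site
#'
#' Runs the regression, projection, deviation, DQ and classification in one
#' call.
#'
#' @param series Surface series tibble.
#' @param gw A `gw_endmember` object (or a list with `rn_dpm_l` and
#'   `pco2_uatm` means).
#' @return A `mixing_result` list (slope, intercept, r, projected pCO2, D,
#'   DQ, `within_band`, `class`).
#' @export
mixing_analysis <- function(series, gw) {
  reg <- mixing_regression(series)
  rn_gw <- if (inherits(gw, "gw_endmember")) endmember_mean(gw, "rn_dpm_l")
           else gw$rn_dpm_l
  pco2_gw <- if (inherits(gw, "gw_endmember")) endmember_mean(gw, "pco2_uatm")
             else gw$pco2_uatm
  D <- deviation(reg$slope_S, reg$intercept_In, rn_gw, pco2_gw)
  DQ <- deviation_quotient(D, pco2_gw)
  structure(list(
    slope_S = reg$slope_S, intercept_In = reg$intercept_In, r = reg$r,
    n = reg$n, rn_gw_mean = rn_gw, pco2_gw_mean = pco2_gw,
    projected_pco2 = reg$slope_S * rn_gw + reg$intercept_In,
    D = D, DQ = DQ, within_band = DQ >= -100 & DQ <= 100,
    class = classify_mixing(DQ)
  ), class = "mixing_result")
}
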