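test_that("correlation summary applies the moderate and significance criteria", {
  n <- 50
  set.seed(1)
  rn <- runif(n, 0, 10)
  s <- make_surface(n, rn = rn, pco2 = 2 * rn + 5, salinity = 35)
  cs <- correlation_summary(s)
  rn_row <- cs[cs$pair == "pco2_vs_rn", ]
  expect_equal(rn_row$r, 1, tolerance = 1e-12)
  expect_true(rn_row$moderate && rn_row$significant)
  # constant salinity: undefined pair, flagged
  sal_row <- cs[cs$pair == "pco2_vs_salinity", ]
  expect_true(sal_row$undefined)
  expect_true(is.na(sal_row$r))
})

test_that("independent white noise rarely shows spurious correlation", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    s <- make_surface(1000, rn = rnorm(1000), pco2 = rnorm(1000))
    r <- correlation_summary(s)
    rn_row <- r[r$pair == "pco2_vs_rn", ]
    if (abs(rn_row$r) < 0.1 && rn_row$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("CUSUM standardizes with the population sd and sums to zero", {
  cv <- cusum_driver_response(c(1, 2, 3), c(1, 2, 3))
  # z = (x - 2)/sqrt(2/3)
  expect_equal(cv$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(cv$s, c(-1.2247, -1.2247, 0), tolerance = 1e-4)

  # constant response: flat flag, s identically zero
  cv0 <- cusum_driver_response(c(1, 2, 3), c(5, 5, 5))
  expect_true(cv0$flat)
  expect_equal(cv0$s, c(0, 0, 0))

  # final sum is zero for random fixtures
  set.seed(3)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    cvr <- cusum_driver_response(runif(n), rnorm(n, 100, 20))
    expect_lt(abs(cvr$s[n]), 1e-9)
  }
})

test_that("CUSUM is invariant to affine response and monotone driver maps", {
  set.seed(4)
  driver <- runif(50); response <- rnorm(50)
  a <- cusum_driver_response(driver, response)
  b <- cusum_driver_response(driver, 3 * response + 7)  # affine response
  expect_equal(a$s, b$s, tolerance = 1e-12)
  c_ <- cusum_driver_response(exp(2 * driver), response) # monotone driver
  expect_equal(a$s, c_$s, tolerance = 1e-12)
})

test_that("CUSUM changepoint finds V-shaped breaks and skips monotone curves", {
  # response steps up only above driver = 5: the cumulative sum is an
  # exact V with its vertex at the threshold
  set.seed(5)
  driver <- seq(0.1, 10, length.out = 200)
  response <- ifelse(driver > 5, 140, 100) + rnorm(200, 0, 1)
  cv <- cusum_driver_response(driver, response)
  cp <- cusum_changepoint(cv)
  expect_lt(abs(cp - 5), 0.25)  # within one rank position of the break

  # monotone response: no changepoint
  cv2 <- cusum_driver_response(driver, 10 * driver + rnorm(200, 0, 0.1))
  expect_true(is.na(cusum_changepoint(cv2)))

  # flat curve: none
  cv3 <- cusum_driver_response(driver, rep(1, 200))
  expect_true(is.na(cusum_changepoint(cv3)))

  expect_error(cusum_changepoint(cusum_driver_response(1:5, rnorm(5))),
               "at least 10")
})

test_that("tidal extremes of a sinusoid land at the analytic times", {
  period_h <- 12.42
  n <- 2 * 144  # 2 days at 10-min steps
  t_h <- seq(0, by = 1 / 6, length.out = n)
  s <- make_surface(n, dt_min = 10, depth = 2 + 0.5 * sin(2 * pi * t_h / period_h))
  ex <- detect_tidal_extremes(s)
  expect_false(attr(ex, "nontidal"))
  # analytic highs at period*(1/4 + k), lows at period*(3/4 + k)
  t_ex_h <- (as.numeric(ex$time) - as.numeric(s$timestamp[1])) / 3600
  for (i in seq_len(nrow(ex))) {
    anal <- if (ex$kind[i] == "high") period_h * (0.25 + 0:3)
            else period_h * (0.75 + 0:3)
    expect_lt(min(abs(t_ex_h[i] - anal)), 1 / 6 + 1e-9)  # within one sample
  }
  # alternation enforced
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))

  # constant depth: nontidal, empty list
  s0 <- make_surface(100, depth = 2)
  ex0 <- detect_tidal_extremes(s0)
  expect_true(attr(ex0, "nontidal"))
  expect_equal(nrow(ex0), 0)

  # 5 % white noise does not change the extreme count
  set.seed(6)
  s_noisy <- s
  s_noisy$depth_m <- s$depth_m * (1 + rnorm(n, 0, 0.05))
  ex_n <- detect_tidal_extremes(s_noisy)
  expect_equal(nrow(ex_n), nrow(ex))
})

test_that("peak-hour means average the +/- 1 h bracket", {
  s <- make_surface(25, dt_min = 30, pco2 = seq(100, 580, by = 20))
  # single event exactly on a sample with a linear ramp: mean = midpoint
  ev <- tibble::tibble(time = s$timestamp[13], kind = "low")
  pm <- peak_hour_means(s, ev)
  expect_equal(pm$pco2_uatm, s$pco2_uatm[13])  # ramp symmetric around event
  expect_equal(pm$n_samples, 5L)               # 13 +/- 2 samples of 30 min

  # event with an empty window is skipped with zero samples
  ev2 <- tibble::tibble(time = s$timestamp[25] + 86400, kind = "high")
  pm2 <- peak_hour_means(s, ev2)
  expect_equal(pm2$n_samples, 0L)
})

test_that("tidal and diel indices follow their defining arithmetic", {
  # engineered record: pCO2 is 120 around the low tide, 80 around the high
  n <- 6 * 24  # one day at 10-min steps
  t_h <- seq(0, by = 1 / 6, length.out = n)
  pco2 <- rep(100, n)
  pco2[abs(t_h - 4) <= 1] <- 120    # low tide at 04:00
  pco2[abs(t_h - 9) <= 1] <- 80     # high tide at 09:00
  pco2[abs(t_h - 12) <= 1] <- 90    # day anchor 12:00
  pco2[t_h <= 1] <- 110             # night anchor 00:00
  s <- make_surface(n, dt_min = 10, pco2 = pco2)
  events <- tibble::tibble(
    time = s$timestamp[1] + c(4, 9) * 3600, kind = c("low", "high"))
  idx <- tidal_diel_indices(s, events, "pco2")
  eta_bar <- mean(pco2)
  expect_equal(idx$eta_l, 120)
  expect_equal(idx$eta_h, 80)
  expect_equal(idx$tei, (80 - 120) / (2 * eta_bar), tolerance = 1e-12)
  expect_equal(idx$dei, (90 - 110) / (2 * eta_bar), tolerance = 1e-12)
  expect_equal(idx$dominance, abs(idx$tei) / abs(idx$dei))

  # scale invariance: multiplying the parameter by c leaves both unchanged
  s2 <- s; s2$pco2_uatm <- 3.7 * s$pco2_uatm
  idx2 <- tidal_diel_indices(s2, events, "pco2")
  expect_equal(idx2$tei, idx$tei, tolerance = 1e-12)
  expect_equal(idx2$dei, idx$dei, tolerance = 1e-12)
})

test_that("generator output locks the driver-analysis sign conventions", {
  sim <- simulate_box_model(synth_preset("tidal_dominated", seed = 11))
  s <- sim$series
  cs <- correlation_summary(s)
  # radon injected at low tide raises pCO2: positive correlation
  expect_gt(cs$r[cs$pair == "pco2_vs_rn"], 0)
  # pCO2 peaks at low tide: negative TEI
  idx <- tidal_diel_indices(s, NULL, "pco2")
  expect_lt(idx$tei, 0)
})
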