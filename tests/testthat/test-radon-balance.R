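test_that("steady-state budget solves the radon balance by hand algebra", {
  # balanced budget: sinks equal the non-groundwater sources
  terms <- radon_budget_terms(rn_gw = 1e5, a = 100, v = 1000, d_dif = 10)
  # d_dif*a = 1000 dpm/day source; give an equal evasion sink
  est <- steady_state_sgd(terms, rn = 0, j_atm_areal = 10)
  expect_equal(est$f_gw, 0)

  # decay-only sink: F_gw = rn * lambda * v / rn_gw
  terms2 <- radon_budget_terms(rn_gw = 1e5, a = 100, v = 1000)
  est2 <- suppressWarnings(steady_state_sgd(terms2, rn = 1000))
  expect_equal(est2$f_gw, 1000 * RN222_LAMBDA * 1000 / 1e5,
               tolerance = 1e-12)
  expect_equal(est2$f_gw, 1.81286, tolerance = 1e-4)
  expect_equal(est2$sgd_rate, 100 * est2$f_gw / 100)

  # doubling the end-member halves the discharge
  terms3 <- radon_budget_terms(rn_gw = 2e5, a = 100, v = 1000)
  est3 <- suppressWarnings(steady_state_sgd(terms3, rn = 1000))
  expect_equal(est3$f_gw, est2$f_gw / 2)

  # negative results clip to zero with a flag
  terms4 <- radon_budget_terms(rn_gw = 1e5, a = 100, v = 1000, d_dif = 1e5)
  est4 <- suppressWarnings(steady_state_sgd(terms4, rn = 0))
  expect_equal(est4$f_gw, 0)
  expect_equal(est4$n_clipped, 1L)
})

test_that("non-steady budget recovers closed-form storage cases", {
  # constant radon, constant depth, no sinks: F_gw = 0 throughout
  s <- make_surface(25, dt_min = 60, rn = 1, depth = 2, wind = 0)
  terms <- radon_budget_terms(rn_gw = 1e5, a = 1, lambda222 = 0)
  est <- nonsteady_sgd(s, terms)
  expect_true(all(abs(est$per_step$f_gw_m3_d) < 1e-9))

  # linear radon rise, all other terms zero: F_gw = V dC/dt / rn_gw
  rn <- seq(1, 2, length.out = 25)          # +1 dpm/L over 24 h
  s2 <- make_surface(25, dt_min = 60, rn = rn, depth = 2, wind = 0)
  est2 <- nonsteady_sgd(s2, terms)
  expected <- 2 * 1000 / 1e5                # V * (dC 1000 dpm/m3/day) / rn_gw
  expect_equal(unname(est2$per_step$f_gw_m3_d),
               rep(expected, 24), tolerance = 1e-9)
  expect_equal(est2$f_gw, expected, tolerance = 1e-9)

  # budget closure: unclipped residuals vanish
  expect_true(all(abs(est2$per_step$residual) < 1e-9 * 1e5))

  expect_error(nonsteady_sgd(s2[1:2, ], terms), "short")
})

test_that("steady-state equals the non-steady time-mean for stationary input", {
  s <- make_surface(49, dt_min = 30, rn = 3, depth = 2, wind = 4)
  meta <- site_metadata("x", "estuary", atm_rn = 100, area_A = 1,
                        volume_V = 2)
  terms <- radon_budget_terms(rn_gw = 1e5, a = 1, v = 2, q_ex = 0.5,
                              rn_offshore = 50)
  alpha <- rn_partition_alpha(25, 35)
  k_rn <- gas_transfer_velocity(4, schmidt_number(25, 35, "Rn"))
  j_areal <- radon_evasion(k_rn, 3000, 100, alpha)
  ss <- steady_state_sgd(terms, rn = 3000, j_atm_areal = j_areal)
  ns <- nonsteady_sgd(s, terms, meta)
  expect_equal(ns$f_gw, ss$f_gw, tolerance = 1e-9)
})

test_that("tidal-cycle integration gives identical estimates for identical cycles", {
  # explicitly periodic record: three identical 12-h cycles
  n <- 3 * 72 + 1
  t_h <- seq(0, by = 1 / 6, length.out = n)
  depth <- 2 + 0.5 * sin(2 * pi * t_h / 12)
  rn <- 3 + 1 * sin(2 * pi * t_h / 12 - 1)
  s <- make_surface(n, dt_min = 10, rn = rn, depth = depth, wind = 2)
  meta <- site_metadata("x", "mangrove", atm_rn = 0, area_A = 1,
                        volume_V = 2)
  terms <- radon_budget_terms(rn_gw = 1e5, a = 1, q_ex = 0.3)
  est <- tidal_cycle_integrated_sgd(s, terms, meta)
  percyc <- est$per_step
  expect_gte(nrow(percyc), 2)
  expect_equal(percyc$f_gw_m3_d[1], percyc$f_gw_m3_d[2], tolerance = 1e-6)
  # start inventory = end inventory: storage residual ~ 0 vs budget scale
  expect_lt(abs(percyc$storage_residual[1]),
            1e-6 * est$f_gw * terms$rn_gw + 1e-6)
})

test_that("box-model simulations are recovered by both time-dependent budgets", {
  meta <- site_metadata("x", "estuary", atm_rn = 100, area_A = 1,
                        volume_V = 2)
  for (rate in c(5, 20)) {
    cfg <- synth_config(seed = 30 + rate, sgd_base = rate,
                        sgd_tidal_gain = 0, noise_cv = 0)
    sim <- simulate_box_model(cfg)
    terms <- radon_budget_terms(
      rn_gw = cfg$gw_rn * 1000, a = 1, q_ex = cfg$flushing_rate,
      rn_offshore = rn_partition_alpha(25, 35) * cfg$atm_rn)
    ns <- nonsteady_sgd(sim$series, terms, meta)
    tc <- tidal_cycle_integrated_sgd(sim$series, terms, meta)
    expect_lt(abs(ns$sgd_rate - rate) / rate, 0.15)
    expect_lt(abs(tc$sgd_rate - rate) / rate, 0.15)
  }
})

test_that("Monte Carlo uncertainty behaves like the delta method and is seeded", {
  terms <- radon_budget_terms(rn_gw = 1e5, a = 100, v = 1000)
  est_fn <- function(tr) suppressWarnings(steady_state_sgd(tr, rn = 1000))

  # zero spreads: zero uncertainty
  mc0 <- monte_carlo_uncertainty(est_fn, terms, list(rn_gw = 0), n = 100,
                                 seed = 1)
  expect_equal(mc0$uncertainty_pct, 0)

  # only rn_gw perturbed with small CV: output CV matches to first order
  # (F ~ 1/rn_gw, delta method: CV_out ~ CV_in at small CV)
  mc <- monte_carlo_uncertainty(est_fn, terms, list(rn_gw = 0.05 * 1e5),
                                n = 4000, seed = 2)
  expect_equal(mc$uncertainty_pct, 5, tolerance = 0.15)

  # reproducible under a fixed seed
  mc_a <- monte_carlo_uncertainty(est_fn, terms, list(rn_gw = 2e4), n = 200,
                                  seed = 9)
  mc_b <- monte_carlo_uncertainty(est_fn, terms, list(rn_gw = 2e4), n = 200,
                                  seed = 9)
  expect_identical(mc_a$draws, mc_b$draws)

  # discharge pinned at zero: undefined uncertainty, flagged
  terms0 <- radon_budget_terms(rn_gw = 1e5, a = 100, v = 1000, d_dif = 1e5)
  est0 <- function(tr) suppressWarnings(steady_state_sgd(tr, rn = 0))
  mcz <- monte_carlo_uncertainty(est0, terms0, list(rn_gw = 10), n = 100,
                                 seed = 3)
  expect_true(is.na(mcz$uncertainty_pct))
  expect_false(is.null(mcz$flag))
})
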