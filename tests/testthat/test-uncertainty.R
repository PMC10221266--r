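test_that("sensor noise is the sample s.d. of a constant-condition segment", {
  expect_equal(estimate_sensor_noise(rep(1.2, 10))$me_x_v, 0)
  expect_equal(estimate_sensor_noise(c(1.0, 1.001))$me_x_v, 0.001 / sqrt(2),
               tolerance = 1e-10)
  set.seed(61)
  big <- estimate_sensor_noise(rnorm(1e4, 1.2, 2e-4))
  expect_equal(big$me_x_v, 2e-4, tolerance = 0.05)
  expect_error(estimate_sensor_noise(1.2), class = "bapscal_error_data")
  with_b <- estimate_sensor_noise(c(1, 1.001), b = 250.1)
  expect_equal(with_b$equivalent_measurand_error,
               250.1 * 0.001 / sqrt(2), tolerance = 1e-10)
})

test_that("noise converts to measurand errors and detection limits", {
  expect_equal(noise_to_measurand(0.0002, 250.1), 0.05, tolerance = 0.01)
  expect_equal(noise_to_measurand(0.00015, 14.83), 0.002, tolerance = 0.15)
  expect_identical(noise_to_measurand(0, 250.1), 0)
  expect_equal(detection_limit(0.05), 0.15)
  expect_identical(detection_limit(0), 0)
  expect_equal(detection_limit(0.005), 0.015)
})

test_that("pressure me_y scales with the measured difference", {
  expect_equal(pressure_me_y(26), 0.052)
  expect_identical(pressure_me_y(0), 0)
  expect_equal(pressure_me_y(6), 0.012)
  expect_lt(pressure_me_y(6) / 6, 0.01) # < 1% of a 6 hPa change
  expect_equal(pressure_me_y(c(13, 39), average = TRUE), 0.052)
})

test_that("variance decomposition conserves and validates the budget", {
  d <- decompose_variance(0.154, sqrt(0.003))
  expect_equal(d$t2, 0.151, tolerance = 1e-12)
  expect_equal(d$sigma2, d$me_y2 + d$t2, tolerance = 1e-15)
  expect_equal(decompose_variance(0.5, 0)$t2, 0.5)
  expect_error(decompose_variance(0.1, 1), class = "bapscal_error_budget")
  co2 <- decompose_variance(10e-6, sqrt(2e-6))
  expect_equal(co2$me_y_share, 0.20, tolerance = 1e-12)
})

test_that("Monte Carlo me_y vanishes with the input errors and is reproducible", {
  pr <- baps_protocol(n_steps = 4)
  zero <- mc_input_spec(v_head_sd_ml = 0, p_sd_pa = 0, dp_rel_sd = 0,
                        t_sd_k = 0, include_slope_error = FALSE,
                        n_sim = 20, seed = 1)
  mc0 <- mc_concentration_errors(pr, zero)
  expect_equal(mc0$me_y_o2_volpct, rep(0, 5))
  expect_equal(mc0$me_y_co2_umol_ml, rep(0, 5))
  spec <- mc_input_spec(n_sim = 50, seed = 99)
  a <- mc_concentration_errors(pr, spec)
  b <- mc_concentration_errors(pr, spec)
  expect_identical(a$me_y_o2_volpct, b$me_y_o2_volpct)
  expect_error(mc_concentration_errors(pr, mc_input_spec(n_sim = 1)),
               class = "bapscal_error_domain")
})

test_that("Monte Carlo me_y scales linearly with the input s.d.s", {
  pr <- baps_protocol()
  scaled_spec <- function(f, seed) {
    mc_input_spec(v_head_sd_ml = 10 * f, p_sd_pa = 5 * f, dp_rel_sd = 0.002 * f,
                  t_sd_k = 0.1 * f, slope_rel_error = 0.0042 * f,
                  n_sim = 300, seed = seed)
  }
  full <- mc_concentration_errors(pr, scaled_spec(1, 7))
  half <- mc_concentration_errors(pr, scaled_spec(0.5, 8))
  ratio_o2 <- mean(half$me_y_o2_volpct[-1]) / mean(full$me_y_o2_volpct[-1])
  ratio_co2 <- mean(half$me_y_co2_umol_ml[-1]) / mean(full$me_y_co2_umol_ml[-1])
  expect_equal(ratio_o2, 0.5, tolerance = 0.15)
  expect_equal(ratio_co2, 0.5, tolerance = 0.15)
})

test_that("gas-error propagation is exact in its closed form", {
  pr <- baps_protocol()
  none <- propagate_gas_error(pr, 0)
  expect_equal(none$per_step$dev_o2_volpct, rep(0, 9))
  expect_equal(none$coefficients$db, c(0, 0))

  ge <- propagate_gas_error(pr, 0.02)
  expect_equal(ge$per_step$dev_o2_volpct[1], 0.41, tolerance = 1e-12)
  # O2 deviation decays geometrically with the exchange count
  q <- pr$dp_pa / pr$chamber$p_pa
  expect_equal(ge$per_step$dev_o2_volpct, 0.41 * (1 - q)^(0:8),
               tolerance = 1e-9)
  # OLS refit of scaled measurands shifts the coefficients by the same
  # relative amount: db = rel * |b|
  truths <- default_sensor_truths()
  expect_equal(ge$coefficients$db[ge$coefficients$sensor == "o2"],
               0.02 * truths$o2$b, tolerance = 1e-6)
  expect_equal(ge$coefficients$db[ge$coefficients$sensor == "co2"],
               0.02 * truths$co2$b, tolerance = 1e-6)
  # deviations scale linearly in the relative gas error
  ge_half <- propagate_gas_error(pr, 0.01)
  expect_equal(ge_half$per_step$dev_o2_volpct,
               ge$per_step$dev_o2_volpct / 2, tolerance = 1e-9)
})

test_that("MC coefficient errors behave and stay below the OLS standard errors", {
  pr <- baps_protocol()
  zero <- mc_input_spec(v_head_sd_ml = 0, p_sd_pa = 0, dp_rel_sd = 0,
                        t_sd_k = 0, include_slope_error = FALSE,
                        n_sim = 10, seed = 3)
  cz <- mc_coefficient_errors(pr, zero)
  expect_equal(cz$sd_a, c(0, 0), tolerance = 1e-12)
  expect_equal(cz$sd_b, c(0, 0), tolerance = 1e-12)
  expect_error(mc_coefficient_errors(pr, mc_input_spec(n_sim = 1)),
               class = "bapscal_error_domain")

  # on a matched synthetic calibration, the me_y-induced coefficient
  # scatter is smaller than the OLS standard errors of a realistic fit
  cc <- mc_coefficient_errors(pr, mc_input_spec(n_sim = 200, seed = 17))
  run <- simulate_calibration_run(protocol = pr, seed = 17)
  for (sensor in c("o2", "co2")) {
    f <- fit_ols(run$datasets[[sensor]])
    expect_lt(cc$sd_a[cc$sensor == sensor], f$se_a)
    expect_lt(cc$sd_b[cc$sensor == sensor], f$se_b)
  }
})
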