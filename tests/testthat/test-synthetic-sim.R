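test_that("noise-free simulated calibrations round-trip the true coefficients", {
  truths <- list(
    pressure = sensor_truth(699.6, 250.1),
    o2 = sensor_truth(-3.69, 14.83),
    co2 = sensor_truth(-0.015, 0.52)
  )
  run <- simulate_calibration_run(truths, replicates = 3,
                                  me_y = c(pressure = 0, o2 = 0, co2 = 0),
                                  seed = 1)
  for (sensor in names(truths)) {
    f <- fit_ols(run$datasets[[sensor]])
    expect_equal(f$a, truths[[sensor]]$a, tolerance = 1e-9)
    expect_equal(f$b, truths[[sensor]]$b, tolerance = 1e-9)
  }
})

test_that("simulated runs are bit-identical under a fixed seed", {
  a <- simulate_calibration_run(seed = 42)
  b <- simulate_calibration_run(seed = 42)
  expect_identical(a$datasets$o2$signal_v, b$datasets$o2$signal_v)
  expect_identical(a$log, b$log)
  inc1 <- simulate_incubation(400, 75, seed = 42)
  inc2 <- simulate_incubation(400, 75, seed = 42)
  expect_identical(inc1$signal_co2_v, inc2$signal_co2_v)
})

test_that("OLS confidence intervals attain nominal coverage on simulated runs", {
  n_seeds <- 200
  hits <- vapply(seq_len(n_seeds), function(s) {
    d <- make_linear_data(a = 700, b = 250, sd_y = 0.4, k = 9, seed = 5000 + s)
    f <- fit_ols(d)
    f$ci_b[1] <= 250 && 250 <= f$ci_b[2]
  }, logical(1))
  cover <- mean(hits)
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)
})

test_that("quadratic sensor truth triggers the linearity diagnostic", {
  # curvature must be detectable above the measurand scatter: the O2
  # span of the protocol covers ~0.12 V, so a quadratic term of 5 Vol%/V^2
  # deflects the midpoint by ~8e-3 Vol%, well above a 1e-3 Vol% scatter
  truths <- default_sensor_truths()
  truths$o2$nonlin_c <- 5
  truths$o2$residual_sd <- 1e-3
  hits <- vapply(1:30, function(s) {
    run <- simulate_calibration_run(truths, replicates = 3,
                                    me_y = c(pressure = 0.052, o2 = 0,
                                             co2 = 0.0013),
                                    seed = 6000 + s)
    residual_trend_test(run$datasets$o2)$nonlinear
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  # and the linear default does not trip the diagnostic unduly
  base <- vapply(1:30, function(s) {
    run <- simulate_calibration_run(default_sensor_truths(), replicates = 3,
                                    seed = 6500 + s)
    residual_trend_test(run$datasets$o2)$nonlinear
  }, logical(1))
  expect_lt(mean(base), 0.2)
})

test_that("coefficient histories apply drift and scatter as configured", {
  truth <- sensor_truth(a = 700, b = 250, drift_a = 0, drift_b = 0)
  h0 <- simulate_coefficient_history(truth, n_years = 3, per_year = 2,
                                     scatter_a = 0, scatter_b = 0, seed = 1)
  expect_equal(unique(h0$a), 700)
  expect_equal(unique(h0$b), 250)
  expect_true(all(diff(as.numeric(h0$date)) > 0))
  truth_d <- sensor_truth(a = 700, b = 250, drift_a = 0.05)
  hd <- simulate_coefficient_history(truth_d, n_years = 4, per_year = 2,
                                     scatter_a = 0, scatter_b = 0, seed = 1)
  expect_equal(hd$a[8], 700 * (1 + 0.05 * 3.5), tolerance = 1e-9)
})

test_that("history scatter matched to observed variability reproduces the CVs", {
  # emulate the multi-year O2 record: scatter equal to the observed s.d.s
  st <- baps_example_stability()
  o2 <- st[st$sensor == "o2", ]
  truth <- sensor_truth(a = o2$mean_a, b = o2$mean_b)
  cvs <- vapply(1:40, function(s) {
    h <- simulate_coefficient_history(truth, n_years = 3, per_year = 2,
                                      scatter_a = o2$sd_a, scatter_b = o2$sd_b,
                                      seed = 7000 + s)
    s <- stability_summary(h)
    s$cv_pct[s$coefficient == "b"]
  }, numeric(1))
  target <- 100 * o2$sd_b / abs(o2$mean_b)
  expect_lt(abs(mean(cvs) - target), 3 * sd(cvs) / sqrt(40) + 0.3)
})

test_that("zero-rate incubations are flat and out-of-range CO2 warns", {
  inc <- simulate_incubation(0, 0, noise = FALSE)
  expect_lt(diff(range(inc$o2_volpct)), 1e-9)
  expect_lt(diff(range(inc$p_hpa)), 1e-9)
  expect_warning(
    simulate_incubation(4000, 0, duration_h = 3, noise = FALSE),
    "measuring range")
})

test_that("simulated signal logs parse cleanly through the standard reader", {
  run <- simulate_calibration_run(seed = 9)
  path <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(run$log), path, row.names = FALSE)
  parsed <- read_sensor_log(path)
  expect_equal(nrow(parsed$log), nrow(run$log))
  expect_equal(nrow(parsed$rejects), 0)
  expect_equal(parsed$log$signal_v, run$log$signal_v, tolerance = 1e-12)
  unlink(path)
})
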