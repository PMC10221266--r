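test_that("OLS reproduces an exact line and standard t machinery", {
  d <- calibration_data(1:3, c(0, 1, 2), c(1, 3, 5))
  f <- fit_ols(d)
  expect_equal(f$a, 1, tolerance = 1e-10)
  expect_equal(f$b, 2, tolerance = 1e-10)
  expect_equal(f$se_b, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_ols(calibration_data(1:3, c(1, 1, 1), c(1, 2, 3))),
               class = "bapscal_error_data")
  expect_error(fit_ols(calibration_data(1:2, c(0, 1), c(1, 3))),
               class = "bapscal_error_data")
})

test_that("t critical values match the t distribution", {
  expect_equal(t_critical(7), 2.365, tolerance = 5e-4)
  expect_equal(t_critical(1e9), 1.960, tolerance = 1e-3)
  expect_equal(t_critical(1), 12.706, tolerance = 1e-4)
  expect_error(t_critical(7, level = 1.2), class = "bapscal_error_domain")
})

test_that("noisy synthetic calibration recovers the true slope within its CI", {
  d <- make_linear_data(a = 700, b = 250, sd_y = 0.4, k = 9, seed = 11)
  f <- fit_ols(d)
  expect_equal(f$df, 7L)
  expect_equal(f$t_crit, 2.365, tolerance = 5e-4)
  expect_true(f$ci_b[1] <= 250 && 250 <= f$ci_b[2])
  # residuals of an intercept model sum to zero
  expect_equal(sum(f$residuals), 0, tolerance = 1e-10)
  # CI width reconstructs exactly from t_crit and se_b
  expect_equal(diff(f$ci_b), 2 * t_critical(7) * f$se_b, tolerance = 1e-12)
  # tidy/glance expose the same numbers
  td <- tidy(f)
  expect_equal(td$estimate, c(f$a, f$b))
  expect_equal(glance(f)$sigma2, f$sigma2)
})

test_that("OLS is equivariant under affine rescaling of the signal", {
  d <- make_linear_data(sd_y = 0.4, seed = 21)
  f1 <- fit_ols(d)
  d2 <- dplyr::mutate(d, signal_v = 3 * signal_v + 0.7)
  f2 <- fit_ols(calibration_data(d2$point_id, d2$signal_v, d2$measurand))
  expect_equal(f2$b, f1$b / 3, tolerance = 1e-9)
  expect_equal(f2$a, f1$a - f1$b * 0.7 / 3, tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("Durbin-Watson follows its definition and flags structure", {
  expect_equal(durbin_watson(rep(0.5, 6)), 0)
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  set.seed(31)
  expect_equal(durbin_watson(rnorm(5000)), 2, tolerance = 0.1)
  expect_error(durbin_watson(rep(0, 4)), class = "bapscal_error_domain")
  expect_error(durbin_watson(1), class = "bapscal_error_data")
  perm <- durbin_watson(c(1, -1, 1, -1, 1, -1, 1, -1), permutation_p = TRUE)
  expect_lt(perm$p_value, 0.2)
})

test_that("Durbin-Watson agrees with the reference implementation", {
  skip_if_not_installed("lmtest")
  d <- collapse <- make_linear_data(sd_y = 1, seed = 41)
  pts <- dplyr::summarise(dplyr::group_by(d, point_id),
                          x = mean(signal_v), y = measurand[1])
  m <- lm(y ~ x, data = pts[order(pts$x), ])
  expect_equal(durbin_watson(residuals(m)),
               unname(lmtest::dwtest(m)$statistic), tolerance = 1e-10)
})

test_that("polynomial calibration evaluates by Horner's scheme", {
  expect_equal(evaluate_calibration(polynomial_calibration(a = 0, b = 1), 0.42),
               0.42)
  expect_equal(evaluate_calibration(polynomial_calibration(a = 699.6, b = 250.1),
                                    1.2), 999.72)
  expect_equal(evaluate_calibration(polynomial_calibration(a = 0, b = 0), 5), 0)
  cal <- polynomial_calibration(a = 1, b = 2, c = 3, d = 4, e = 5)
  x <- 0.7
  expect_equal(evaluate_calibration(cal, x),
               1 + 2 * x + 3 * x^2 + 4 * x^3 + 5 * x^4, tolerance = 1e-12)
})

test_that("relative slope errors reproduce the published quality figures", {
  expect_equal(relative_se_b(list(b = 250.1, se_b = 1.04)), 0.42,
               tolerance = 0.01)
  expect_equal(relative_se_b(list(b = 0.52, se_b = 0.0020)), 0.385,
               tolerance = 0.01)
  expect_equal(relative_se_b(list(b = 5, se_b = 0)), 0)
  expect_error(relative_se_b(list(b = 0, se_b = 1)),
               class = "bapscal_error_domain")
})

test_that("functional model equals OLS when replicates are identical", {
  d <- make_linear_data(sd_y = 0.3, k = 6, l = 3, me_x = 0, seed = 51)
  fo <- fit_ols(d)
  ff <- fit_functional(d)
  expect_equal(ff$a, fo$a, tolerance = 1e-8)
  expect_equal(ff$b, fo$b, tolerance = 1e-8)
  expect_equal(ff$sigma_z2, 0)
  expect_error(fit_functional(make_linear_data(k = 5, l = 1)),
               class = "bapscal_error_data")
})

test_that("functional model recovers generative parameters with signal noise", {
  n_rep <- 60
  fits <- vapply(seq_len(n_rep), function(s) {
    d <- make_linear_data(a = 700, b = 250, sd_y = 0.5, k = 9, l = 10,
                          me_x = 0.01, seed = 1000 + s)
    f <- fit_functional(d)
    c(f$a, f$b, f$sigma_z2)
  }, numeric(3))
  m <- rowMeans(fits)
  se <- apply(fits, 1, sd) / sqrt(n_rep)
  expect_lt(abs(m[1] - 700), 3 * se[1])
  expect_lt(abs(m[2] - 250), 3 * se[2])
  expect_lt(abs(m[3] - 1e-4), 3 * se[3])
})

test_that("functional slope is centred on zero under a null response", {
  fits <- vapply(1:40, function(s) {
    set.seed(2000 + s)
    d <- calibration_data(rep(1:8, each = 4),
                          rep(seq(0, 2, length.out = 8), each = 4) +
                            rnorm(32, 0, 0.01),
                          rep(rnorm(8, 10, 0.3), each = 4))
    fit_functional(d)$b
  }, numeric(1))
  expect_lt(abs(mean(fits)), 3 * sd(fits) / sqrt(40))
})

test_that("curvature diagnostic flags quadratic responses but not linear ones", {
  n_seeds <- 60
  flag <- function(nonlin) {
    vapply(seq_len(n_seeds), function(s) {
      set.seed(3000 + s)
      x <- seq(0.5, 2, length.out = 9)
      y <- -3.7 + 14.8 * x + nonlin * x^2 + rnorm(9, 0, 0.01)
      residual_trend_test(calibration_data(1:9, x, y))$nonlinear
    }, logical(1))
  }
  power <- mean(flag(0.2))
  size <- mean(flag(0))
  expect_gt(power, 0.9)
  expect_lt(size, 0.05 + 2 * sqrt(0.05 * 0.95 / n_seeds))
})
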