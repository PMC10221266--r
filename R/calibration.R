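## Calibration-function fitting and diagnostics. Sensor signals (V) are
## related to measurands (hPa, Vol% O2, umol mL^-1 CO2) by y = a + b x;
## OLS via stats::lm on the per-point signal means, plus residual
## diagnostics (Durbin-Watson, curvature check) and polynomial evaluation.

#' Assemble a calibration dataset
#'
#' Builds the standard long-format calibration table: one row per sensor
#' reading, grouped into calibration points (steps) with replicated signal
#' readings and one reference measurand value per point.
#'
#' @param point_id Integer id of the calibration point.
#' @param signal_v Raw sensor signal (V).
#' @param measurand Reference value assigned to the point (sensor units:
#'   hPa, Vol% or umol mL-1).
#' @param me_y Known measurement error (s.d.) of the measurand per point;
#'   recycled.
#' @param replicate_id Replicate index within a point; generated when
#'   missing.
#' @param sensor_kind One of `"pressure"`, `"o2"`, `"co2"` (metadata).
#'
#' @return A tibble of class `calibration_data`.
#' @export
calibration_data <- function(point_id, signal_v, measurand, me_y = 0,
                             replicate_id = NULL,
                             sensor_kind = c("pressure", "o2", "co2")) {
  sensor_kind <- match.arg(sensor_kind)
  check_number(signal_v, "signal_v")
  check_number(measurand, "measurand")
  d <- tibble(point_id = as.integer(point_id), signal_v = signal_v,
              measurand = measurand, me_y = rep_len(me_y, length(signal_v)))
  if (is.null(replicate_id)) {
    d <- dplyr::mutate(dplyr::group_by(d, .data$point_id),
                       replicate_id = dplyr::row_number())
    d <- dplyr::ungroup(d)
  } else {
    d$replicate_id <- as.integer(replicate_id)
  }
  d <- dplyr::relocate(d, "point_id", "replicate_id")
  if (dplyr::n_distinct(d$measurand[!duplicated(d$point_id)]) < 1) {
    stop_data("calibration data must contain at least one point.")
  }
  attr(d, "sensor_kind") <- sensor_kind
  class(d) <- c("calibration_data", class(d))
  d
}

## per-point collapse: signal mean, measurand, me_y
collapse_points <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("point_id", "signal_v", "measurand")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_data(paste0("calibration data lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  d <- dplyr::group_by(data, .data$point_id)
  d <- dplyr::summarise(
    d,
    signal_v = mean(.data$signal_v),
    measurand = .data$measurand[1],
    me_y = if ("me_y" %in% names(data)) .data$me_y[1] else 0,
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(d, .data$signal_v)
}

#' Two-tailed critical value of Student's t
#'
#' @param df Degrees of freedom (>= 1).
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#'
#' @return The critical value `qt(1 - (1 - level)/2, df)`.
#' @examples
#' t_critical(7) # 2.365
#' @export
t_critical <- function(df, level = 0.95) {
  check_number(df, "df", positive = TRUE)
  check_number(level, "level")
  if (any(level <= 0 | level >= 1)) stop_domain("`level` must be in (0, 1).")
  qt(1 - (1 - level) / 2, df)
}

#' Durbin-Watson statistic of an ordered residual sequence
#'
#' `sum(diff(e)^2) / sum(e^2)`, computed on residuals ordered by the
#' signal. Values near 2 indicate no lag-1 autocorrelation; reported
#' descriptively for calibration quality screening. An optional
#' permutation p-value (two-sided, against the null of exchangeable
#' residual order) can be requested.
#'
#' @param residuals Numeric residuals ordered by x (length >= 2).
#' @param permutation_p If `TRUE`, also return a permutation p-value.
#' @param n_perm Number of permutations.
#'
#' @return The statistic (in `[0, 4]`), or a tibble with `dw` and
#'   `p_value` when `permutation_p = TRUE`.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))
#' @export
durbin_watson <- function(residuals, permutation_p = FALSE, n_perm = 999) {
  check_number(residuals, "residuals")
  if (length(residuals) < 2) stop_data("need at least 2 residuals.")
  ss <- sum(residuals^2)
  if (ss == 0) stop_domain("all residuals are zero: Durbin-Watson is undefined.")
  dw <- sum(diff(residuals)^2) / ss
  if (!permutation_p) return(dw)
  perm <- replicate(n_perm, {
    e <- sample(residuals)
    sum(diff(e)^2) / sum(e^2)
  })
  p <- (1 + sum(abs(perm - 2) >= abs(dw - 2))) / (n_perm + 1)
  tibble(dw = dw, p_value = p)
}

#' Ordinary least squares calibration fit
#'
#' Fits the linear calibration `y = a + b x` by OLS, with the signal
#' replicates of each calibration point collapsed to their mean. Reports
#' coefficient standard errors, two-sided confidence intervals
#' `a +/- t_crit se_a` and `b +/- t_crit se_b`, the coefficient of
#' determination, residuals and their variance `sigma2 = RSS / (k - 2)`,
#' and the Durbin-Watson statistic of the signal-ordered residuals.
#'
#' @param data A [calibration_data()] tibble (or any data frame with
#'   columns `point_id`, `signal_v`, `measurand`).
#' @param level Confidence level for the coefficient intervals.
#'
#' @return An object of class `baps_ols` (also `baps_fit`). Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract
#'   coefficient and fit summaries as tibbles, and
#'   [autoplot()][ggplot2::autoplot] for a calibration plot.
#' @examples
#' d <- calibration_data(1:3, c(0, 1, 2), c(1, 3, 5))
#' fit_ols(d)
#' @export
fit_ols <- function(data, level = 0.95) {
  pts <- collapse_points(data)
  k <- nrow(pts)
  if (k < 3) stop_data("OLS calibration needs at least 3 calibration points.")
  if (sd(pts$signal_v) == 0) {
    stop_data("zero signal variance across points: singular design.")
  }
  model <- lm(measurand ~ signal_v, data = pts)
  ## noise-free reference data fits exactly; the perfect-fit warning from
  ## summary.lm is expected there and not informative
  sm <- suppressWarnings(summary(model))
  est <- coef(sm)
  df <- k - 2L
  tc <- t_critical(df, level)
  a <- est["(Intercept)", "Estimate"]
  b <- est["signal_v", "Estimate"]
  se_a <- est["(Intercept)", "Std. Error"]
  se_b <- est["signal_v", "Std. Error"]
  res <- stats::residuals(model)
  structure(
    list(
      a = a, b = b, se_a = se_a, se_b = se_b,
      ci_a = c(a - tc * se_a, a + tc * se_a),
      ci_b = c(b - tc * se_b, b + tc * se_b),
      r_squared = sm$r.squared,
      residuals = unname(res),
      sigma2 = sum(res^2) / df,
      dw = durbin_watson(res),
      df = df, k = k, level = level,
      t_crit = tc,
      sensor_kind = attr(data, "sensor_kind", exact = TRUE) %||% NA_character_,
      points = pts, model = model
    ),
    class = c("baps_ols", "baps_fit")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.baps_ols <- function(x, ...) {
  cat(sprintf("<baps_ols> y = %.4g + %.4g x (k = %d points)\n", x$a, x$b, x$k))
  cat(sprintf("  se_a = %.3g, se_b = %.3g, R2 = %.5f, sigma2 = %.4g, DW = %.2f\n",
              x$se_a, x$se_b, x$r_squared, x$sigma2, x$dw))
  cat(sprintf("  %.0f%% CI(b): [%.4g, %.4g]  (t_crit = %.3f, df = %d)\n",
              100 * x$level, x$ci_b[1], x$ci_b[2], x$t_crit, x$df))
  invisible(x)
}

#' @export
tidy.baps_ols <- function(x, ...) {
  tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(x$se_a, x$se_b),
    statistic = c(x$a / x$se_a, x$b / x$se_b),
    p.value = 2 * pt(-abs(c(x$a / x$se_a, x$b / x$se_b)), x$df),
    conf.low = c(x$ci_a[1], x$ci_b[1]),
    conf.high = c(x$ci_a[2], x$ci_b[2])
  )
}

#' @export
glance.baps_ols <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma2 = x$sigma2, dw = x$dw,
         df = x$df, k = x$k, t_crit = x$t_crit, level = x$level)
}

#' Polynomial calibration coefficients
#'
#' The instrument converts signals to measurands through
#' `y = a + b x + c x^2 + d x^3 + e x^4`; in practice linear calibrations
#' (`c = d = e = 0`) suffice across the sensors' measuring ranges.
#'
#' @param a,b,c,d,e Calibration coefficients.
#'
#' @return An object of class `polynomial_calibration`.
#' @export
polynomial_calibration <- function(a = 0, b = 1, c = 0, d = 0, e = 0) {
  for (nm in c("a", "b", "c", "d", "e")) check_number(get(nm), nm)
  structure(list(a = a, b = b, c = c, d = d, e = e),
            class = "polynomial_calibration")
}

#' @export
print.polynomial_calibration <- function(x, ...) {
  cat(sprintf("<polynomial_calibration> y = %.6g + %.6g x", x$a, x$b))
  if (x$c != 0) cat(sprintf(" + %.3g x^2", x$c))
  if (x$d != 0) cat(sprintf(" + %.3g x^3", x$d))
  if (x$e != 0) cat(sprintf(" + %.3g x^4", x$e))
  cat("\n")
  invisible(x)
}

as_polynomial_calibration <- function(cal) {
  if (inherits(cal, "sensor_truth")) {
    return(polynomial_calibration(a = cal$a, b = cal$b, c = cal$nonlin_c))
  }
  if (inherits(cal, "polynomial_calibration")) return(cal)
  if (inherits(cal, "baps_fit")) return(polynomial_calibration(a = cal$a, b = cal$b))
  if (is.list(cal) && all(c("a", "b") %in% names(cal))) {
    return(polynomial_calibration(a = cal$a, b = cal$b, c = cal$c %||% 0,
                                  d = cal$d %||% 0, e = cal$e %||% 0))
  }
  stop_data("cannot interpret `cal` as a calibration.")
}

#' Evaluate a polynomial calibration
#'
#' Horner evaluation of the quartic calibration polynomial at the given
#' signal(s).
#'
#' @param cal A [polynomial_calibration()], a fitted `baps_fit`, or a list
#'   with elements `a` and `b`.
#' @param signal_v Sensor signal(s) (V).
#'
#' @return Measurand value(s).
#' @examples
#' evaluate_calibration(polynomial_calibration(a = 699.6, b = 250.1), 1.2)
#' @export
evaluate_calibration <- function(cal, signal_v) {
  cal <- as_polynomial_calibration(cal)
  check_number(signal_v, "signal_v")
  ((((cal$e * signal_v + cal$d) * signal_v + cal$c) * signal_v + cal$b) *
     signal_v + cal$a)
}

#' Relative standard error of the calibration slope
#'
#' `100 * se_b / |b|`, the headline quality figure of a calibration: BaPS
#' rate calculations rest on measurand *changes*, so the slope error
#' dominates while the intercept error is of minor importance.
#'
#' @param fit A fitted `baps_fit`, or a list with `b` and `se_b`.
#'
#' @return Relative slope standard error in percent.
#' @examples
#' relative_se_b(list(b = 250.1, se_b = 1.04))
#' @export
relative_se_b <- function(fit) {
  b <- fit$b
  se_b <- fit$se_b
  check_number(b, "b")
  check_number(se_b, "se_b", nonneg = TRUE)
  if (b == 0) stop_domain("relative slope error is undefined for b = 0.")
  100 * se_b / abs(b)
}

#' Residual curvature check for calibration linearity
#'
#' Wald test on a quadratic signal term added to the linear calibration:
#' a significant quadratic coefficient flags a systematic residual trend,
#' i.e. a non-linear sensor response over the calibrated range.
#'
#' @param data A [calibration_data()] tibble.
#' @param alpha Significance level.
#'
#' @return A tibble with the quadratic coefficient estimate, its t
#'   statistic, p-value and the logical `nonlinear`.
#' @export
residual_trend_test <- function(data, alpha = 0.05) {
  pts <- collapse_points(data)
  if (nrow(pts) < 4) stop_data("curvature check needs at least 4 points.")
  model <- lm(measurand ~ signal_v + I(signal_v^2), data = pts)
  est <- coef(summary(model))
  tibble(
    quad_estimate = est["I(signal_v^2)", "Estimate"],
    statistic = est["I(signal_v^2)", "t value"],
    p_value = est["I(signal_v^2)", "Pr(>|t|)"],
    nonlinear = est["I(signal_v^2)", "Pr(>|t|)"] < alpha
  )
}
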