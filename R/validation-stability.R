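## Reference-gas validation of fitted calibrations and temporal stability
## analysis of calibration-coefficient series (drift classification).

#' Two-point reference slope
#'
#' During validation the chamber is flushed consecutively with two
#' reference gases of known composition; the signal means are related to
#' the known concentrations and the resulting two-point slope is compared
#' against the calibration slope.
#'
#' @param signal_v Two signal means (V).
#' @param concentration Two known concentrations (measurand units).
#'
#' @return The slope `diff(concentration) / diff(signal_v)` (measurand
#'   units per V).
#' @examples
#' reference_slope(c(1, 2), c(0.5, 1.49))
#' @export
reference_slope <- function(signal_v, concentration) {
  check_number(signal_v, "signal_v")
  check_number(concentration, "concentration")
  if (length(signal_v) != 2 || length(concentration) != 2) {
    stop_data("reference_slope needs exactly two (signal, concentration) pairs.")
  }
  if (signal_v[1] == signal_v[2]) {
    stop_domain("identical reference signals: the slope is undefined.")
  }
  diff(concentration) / diff(signal_v)
}

#' Compare a calibration slope against a reference slope
#'
#' Tests whether the calibration slope `b` differs from the two-point
#' reference-gas slope. Since a two-point line carries no conventional
#' slope standard error, the test statistic is built on the calibration
#' fit's uncertainty: `t = |b - ref| / se_b` with `df = k - 2`, compared
#' against the two-tailed critical value at level `alpha`. The result is
#' equivalent to checking whether the reference slope falls inside the
#' confidence interval of `b`, which is reported alongside.
#'
#' @param fit A fitted `baps_fit` (needs `b`, `se_b`, `df`), or a list
#'   with those elements.
#' @param ref_slope Reference slope (measurand units per V).
#' @param alpha Significance level (default 0.05).
#'
#' @return A tibble with `difference`, `t`, `t_crit`, `df`,
#'   `significant` and `within_ci_b`.
#' @examples
#' slope_comparison_test(list(b = 14.83, se_b = 0.05, df = 7), 14.96)
#' @export
slope_comparison_test <- function(fit, ref_slope, alpha = 0.05) {
  b <- fit$b; se_b <- fit$se_b; df <- fit$df
  check_number(b, "b"); check_number(ref_slope, "ref_slope")
  check_number(df, "df", positive = TRUE)
  check_number(se_b, "se_b", nonneg = TRUE)
  if (se_b == 0) {
    stop_domain("se_b = 0: the slope comparison test is degenerate.")
  }
  diff <- b - ref_slope
  t_stat <- abs(diff) / se_b
  tc <- t_critical(df, 1 - alpha)
  tibble(difference = diff, t = t_stat, t_crit = tc, df = df,
         significant = t_stat > tc, within_ci_b = t_stat <= tc)
}

check_history <- function(entries, min_n = 2) {
  if (!is.data.frame(entries) || !all(c("a", "b") %in% names(entries))) {
    stop_data("coefficient history needs columns `a` and `b` (and ideally `date`).")
  }
  if (nrow(entries) < min_n) {
    stop_data(sprintf("coefficient history needs at least %d entries.", min_n))
  }
  if ("date" %in% names(entries)) {
    entries <- dplyr::arrange(entries, .data$date)
  }
  entries
}

#' Summary statistics of a calibration-coefficient series
#'
#' Mean, sample standard deviation (n-1) and coefficient of variation
#' (`100 * s.d. / |mean|`) for the intercept and slope of a dated series
#' of repeated calibrations. High slope CVs point at unstable sensor
#' response; high intercept CVs at signal-strength fluctuations.
#'
#' @param entries Data frame with columns `a`, `b` and optionally `date`
#'   (rows are sorted by date when present).
#'
#' @return A tibble with one row per coefficient: `coefficient`, `mean`,
#'   `sd`, `cv_pct`, `n`.
#' @examples
#' stability_summary(data.frame(a = c(699, 700, 701), b = c(250, 251, 249)))
#' @export
stability_summary <- function(entries) {
  entries <- check_history(entries, min_n = 2)
  purrr::map_dfr(c("a", "b"), function(cc) {
    x <- entries[[cc]]
    tibble(coefficient = cc, mean = mean(x), sd = sd(x),
           cv_pct = cv_percent(x), n = length(x))
  })
}

#' @rdname stability_summary
#' @param x Numeric vector.
#' @export
cv_percent <- function(x) {
  check_number(x, "x")
  if (length(x) < 2) stop_data("CV needs at least 2 values.")
  m <- mean(x)
  if (m == 0) stop_domain("CV is undefined for a zero mean.")
  100 * sd(x) / abs(m)
}

#' Classify sensor drift from a coefficient history
#'
#' Applies a Mann-Kendall monotone-trend test (Kendall rank correlation
#' of each coefficient against time, exact for short series) separately
#' to the intercept and slope series of repeated calibrations. A trend in
#' the slope indicates *response drift* (changing sensitivity, the
#' serious failure mode); a trend in the intercept only indicates
#' *signal-strength drift* (offset aging); neither indicates a *stable*
#' sensor. The two per-coefficient tests are Bonferroni-corrected
#' (`alpha / 2` each) so the family-wise false-alarm rate on a stable
#' sensor stays at `alpha`.
#'
#' @param entries Data frame with columns `a`, `b` and optionally `date`;
#'   at least 4 entries.
#' @param alpha Family-wise significance level (default 0.05).
#'
#' @return A tibble with `drift_class` (one of `"stable"`,
#'   `"signal-strength drift"`, `"response drift"`), the per-coefficient
#'   Kendall tau and p-values, and `alpha`.
#' @export
classify_drift <- function(entries, alpha = 0.05) {
  entries <- check_history(entries, min_n = 4)
  check_number(alpha, "alpha", positive = TRUE)
  time <- if ("date" %in% names(entries)) as.numeric(entries$date) else seq_len(nrow(entries))
  mk <- function(x) {
    ct <- suppressWarnings(cor.test(time, x, method = "kendall"))
    c(tau = unname(ct$estimate), p = ct$p.value)
  }
  res_a <- mk(entries$a)
  res_b <- mk(entries$b)
  thr <- alpha / 2
  cls <- if (res_b["p"] < thr) {
    "response drift"
  } else if (res_a["p"] < thr) {
    "signal-strength drift"
  } else {
    "stable"
  }
  tibble(drift_class = cls,
         tau_a = res_a["tau"], p_a = res_a["p"],
         tau_b = res_b["tau"], p_b = res_b["p"],
         alpha = alpha, n = nrow(entries))
}
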