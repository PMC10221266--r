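## Measurement-error quantification: sensor noise (me_x), measurand
## errors (me_y) analytically and by Monte Carlo through the mole
## balance, residual-variance decomposition, and systematic
## calibration-gas error (gasE) propagation.

#' Sensor noise from a constant-condition signal segment
#'
#' The sensor noise `me_x` is the sample standard deviation (n-1
#' denominator) of the raw signal recorded at constant conditions. It
#' bounds the attainable precision of a single reading.
#'
#' @param signal_v Numeric signal readings (V), or a data frame with a
#'   `signal_v` column.
#' @param b Optional calibration slope used to express the noise on the
#'   measurand scale (`|b| * me_x`).
#'
#' @return A tibble with `me_x_v`, `n_readings` and (when `b` is given)
#'   `equivalent_measurand_error`.
#' @examples
#' estimate_sensor_noise(c(1.0, 1.001))
#' @export
estimate_sensor_noise <- function(signal_v, b = NULL) {
  if (is.data.frame(signal_v)) {
    if (!"signal_v" %in% names(signal_v)) {
      stop_data("data frame input needs a `signal_v` column.")
    }
    signal_v <- signal_v$signal_v
  }
  check_number(signal_v, "signal_v")
  if (length(signal_v) < 2) {
    stop_data("sensor-noise estimation needs at least 2 readings.")
  }
  out <- tibble(me_x_v = sd(signal_v), n_readings = length(signal_v))
  if (!is.null(b)) {
    out$equivalent_measurand_error <- noise_to_measurand(out$me_x_v, b)
  }
  out
}

#' Express signal noise on the measurand scale
#'
#' @param me_x_v Signal noise s.d. (V).
#' @param b Calibration slope (measurand units per V).
#'
#' @return `|b| * me_x_v` in measurand units.
#' @examples
#' noise_to_measurand(0.0002, 250.1) # pressure noise in hPa
#' @export
noise_to_measurand <- function(me_x_v, b) {
  check_number(me_x_v, "me_x_v", nonneg = TRUE)
  check_number(b, "b")
  abs(b) * me_x_v
}

#' Detection limit from the noise level
#'
#' A measured change is reliably distinguishable from sensor noise when
#' it exceeds three times the noise level.
#'
#' @param me_x_equivalent Noise expressed in measurand units.
#'
#' @return `3 * me_x_equivalent`.
#' @export
detection_limit <- function(me_x_equivalent) {
  check_number(me_x_equivalent, "me_x_equivalent", nonneg = TRUE)
  3 * me_x_equivalent
}

#' Measurand error of the pressure calibration
#'
#' The reference pressure differences are read from a differential
#' manometer with a stated relative accuracy, so `me_y = rel_accuracy *
#' |dP|`. Because the pressure span of the calibration is small, the mean
#' over the protocol's steps is commonly used as a constant measurement
#' error for the whole range.
#'
#' @param dp_hpa Measured pressure difference(s) (hPa).
#' @param rel_accuracy Relative accuracy of the manometer (default 0.002).
#' @param average If `TRUE`, return the mean over the supplied steps.
#'
#' @return Measurand error(s) in hPa.
#' @examples
#' pressure_me_y(26)          # 0.052 hPa
#' pressure_me_y(c(13, 26, 39), average = TRUE)
#' @export
pressure_me_y <- function(dp_hpa, rel_accuracy = 0.002, average = FALSE) {
  check_number(dp_hpa, "dp_hpa")
  check_number(rel_accuracy, "rel_accuracy", nonneg = TRUE)
  out <- rel_accuracy * abs(dp_hpa)
  if (average) mean(out) else out
}

#' Monte Carlo input specification
#'
#' Standard deviations for the input variables of the gas-exchange mole
#' balance, used when simulating calibration runs to estimate the
#' measurand error `me_y` of the derived O2 and CO2 concentrations. The
#' defaults are the package's documented instrument assumptions: 10 mL on
#' the headspace volume (volume-extension uncertainty), 5 Pa on absolute
#' pressure, a 0.2% relative manometer error on each pressure difference,
#' and 0.1 K on each temperature. The relative standard error of the
#' pressure-calibration slope can additionally be applied to the pressure
#' differences (added in quadrature).
#'
#' @param v_head_sd_ml S.d. of the headspace volume (mL).
#' @param p_sd_pa S.d. of the chamber pressure (Pa).
#' @param dp_rel_sd Relative s.d. of each measured pressure difference.
#' @param t_sd_k S.d. of each temperature (K).
#' @param include_slope_error Add the pressure-calibration slope error to
#'   the dP terms?
#' @param slope_rel_error Relative standard error of the pressure
#'   calibration slope (default 0.0042).
#' @param n_sim Number of simulated calibration runs.
#' @param seed RNG seed for reproducibility (optional).
#'
#' @return An object of class `mc_input_spec`.
#' @export
mc_input_spec <- function(v_head_sd_ml = 10, p_sd_pa = 5, dp_rel_sd = 0.002,
                          t_sd_k = 0.1, include_slope_error = TRUE,
                          slope_rel_error = 0.0042, n_sim = 1000,
                          seed = NULL) {
  for (nm in c("v_head_sd_ml", "p_sd_pa", "dp_rel_sd", "t_sd_k",
               "slope_rel_error")) {
    check_number(get(nm), nm, nonneg = TRUE)
  }
  if (n_sim < 1 || n_sim != round(n_sim)) {
    stop_domain("n_sim must be a positive integer.")
  }
  structure(
    list(v_head_sd_ml = v_head_sd_ml, p_sd_pa = p_sd_pa, dp_rel_sd = dp_rel_sd,
         t_sd_k = t_sd_k, include_slope_error = include_slope_error,
         slope_rel_error = slope_rel_error, n_sim = as.integer(n_sim),
         seed = seed),
    class = "mc_input_spec"
  )
}

## effective s.d. of a measured pressure difference: manometer error and
## (optionally) the pressure-calibration slope error, in quadrature
dp_sd_pa <- function(spec, dp_pa) {
  s2 <- (spec$dp_rel_sd * dp_pa)^2
  if (isTRUE(spec$include_slope_error)) {
    s2 <- s2 + (spec$slope_rel_error * dp_pa)^2
  }
  sqrt(s2)
}

## one perturbed protocol realisation -> per-step concentration table,
## or NULL when a draw is physically infeasible
perturbed_protocol_run <- function(protocol, spec) {
  ch <- protocol$chamber
  v <- ch$v_head_ml + rnorm(1, 0, spec$v_head_sd_ml)
  p <- ch$p_pa + rnorm(1, 0, spec$p_sd_pa)
  t0 <- ch$t_k + rnorm(1, 0, spec$t_sd_k)
  ns <- protocol$n_steps
  sdp <- dp_sd_pa(spec, protocol$dp_pa)
  dpo <- protocol$dp_pa + rnorm(ns, 0, sdp)
  dpi <- protocol$dp_pa + rnorm(ns, 0, sdp)
  tout <- t0 + rnorm(ns, 0, spec$t_sd_k)
  tin <- t0 + rnorm(ns, 0, spec$t_sd_k)
  if (v <= 0 || p <= 0 || t0 <= 0 || any(dpo < 0) || any(dpi < 0) ||
      any(tout <= 0) || any(tin <= 0) || any(dpo >= p)) {
    return(NULL)
  }
  pert <- baps_protocol(initial = protocol$initial,
                        injected = protocol$injected,
                        n_steps = ns, dp_pa = protocol$dp_pa,
                        p_pa = p, t_k = t0, v_head_ml = v)
  tryCatch(
    run_protocol(pert, dp_out_pa = dpo, dp_in_pa = dpi,
                 t_out_k = tout, t_in_k = tin),
    bapscal_error_infeasible = function(e) NULL
  )
}

mc_protocol_runs <- function(protocol, spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  runs <- vector("list", spec$n_sim)
  rejected <- 0L
  max_attempts <- 50L * spec$n_sim + 100L
  attempts <- 0L
  i <- 1L
  while (i <= spec$n_sim) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("too many infeasible Monte Carlo draws; check the input s.d.s.",
            class = "bapscal_error_infeasible")
    }
    run <- perturbed_protocol_run(protocol, spec)
    if (is.null(run)) {
      rejected <- rejected + 1L
      next
    }
    runs[[i]] <- run
    i <- i + 1L
  }
  if (rejected > 0.01 * spec$n_sim) {
    warn(sprintf("%d of %d Monte Carlo draws were physically infeasible and rejected.",
                 rejected, attempts))
  }
  attr(runs, "rejected") <- rejected
  runs
}

#' Monte Carlo measurand errors of the derived concentrations
#'
#' Simulates the gas-exchange calibration many times, each run drawing
#' every input of the mole balance (`V_head`, `P`, `T`, and per-step
#' `dP_out`, `dP_in`, `T_out`, `T_in`) from a normal distribution with
#' the specified standard deviations, and reports the standard deviation
#' across runs of the per-step O2 (Vol%) and CO2 (umol mL-1)
#' concentrations as the measurand error `me_y`. Physically infeasible
#' draws are rejected and counted; more than 1% rejections triggers a
#' warning. Results are reproducible under a fixed `seed` in the spec.
#'
#' @param protocol A [baps_protocol()].
#' @param spec An [mc_input_spec()].
#'
#' @return A tibble with one row per step: `step`, `me_y_o2_volpct`,
#'   `me_y_co2_umol_ml`, with attributes `rejected` (count) and `n_sim`.
#' @export
mc_concentration_errors <- function(protocol, spec = mc_input_spec()) {
  stopifnot(inherits(protocol, "baps_protocol"), inherits(spec, "mc_input_spec"))
  if (spec$n_sim < 2) stop_domain("need n_sim >= 2 to estimate a standard deviation.")
  runs <- mc_protocol_runs(protocol, spec)
  o2 <- purrr::map(runs, "o2_volpct")
  co2 <- purrr::map(runs, "co2_umol_ml")
  o2 <- do.call(cbind, o2)
  co2 <- do.call(cbind, co2)
  out <- tibble(
    step = 0:protocol$n_steps,
    me_y_o2_volpct = apply(o2, 1, sd),
    me_y_co2_umol_ml = apply(co2, 1, sd)
  )
  attr(out, "rejected") <- attr(runs, "rejected")
  attr(out, "n_sim") <- spec$n_sim
  out
}

#' Decompose the residual variance of a calibration
#'
#' Splits the residual variance `sigma2` of a calibration line into the
#' known measurement-error component `me_y^2` and the remaining
#' "individual part" `t2 = sigma2 - me_y^2`, the genuine measurement
#' variability that cannot be reduced by refining the calibration
#' procedure.
#'
#' @param sigma2 Residual variance (squared measurand units).
#' @param me_y Known measurand error s.d. (measurand units).
#'
#' @return A tibble of class `variance_decomposition` with `sigma2`,
#'   `me_y2`, `t2`, `t` and `me_y_share` (fraction of `sigma2` explained
#'   by `me_y^2`).
#' @examples
#' decompose_variance(0.154, sqrt(0.003)) # pressure calibration budget
#' @export
decompose_variance <- function(sigma2, me_y) {
  check_number(sigma2, "sigma2", nonneg = TRUE)
  check_number(me_y, "me_y", nonneg = TRUE)
  me_y2 <- me_y^2
  if (any(me_y2 > sigma2)) {
    abort("me_y^2 exceeds sigma2: the stated measurement error is inconsistent with the observed residual variance.",
          class = "bapscal_error_budget")
  }
  out <- tibble(sigma2 = sigma2, me_y2 = me_y2, t2 = sigma2 - me_y2,
                t = sqrt(sigma2 - me_y2),
                me_y_share = ifelse(sigma2 > 0, me_y2 / sigma2, 0))
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' Systematic calibration-gas error (gasE) propagation
#'
#' The stated relative accuracy of the calibration gas cylinders is a
#' systematic error: it shifts every derived concentration of the
#' affected species by the same relative amount. This function perturbs
#' the initial fill's O2 fraction and the injected mixture's CO2 fraction
#' by `+/- rel_gas_error` (treating the two cylinders as independent),
#' re-runs the mole balance, and reports per step the maximal deviation
#' envelope of the concentrations, plus the induced deviations of the
#' calibration coefficients when the perturbed concentrations are refit
#' against the unchanged sensor signals.
#'
#' Because the mole balance is linear in the source compositions, the O2
#' deviation after `i` exchanges follows the closed form
#' `rel * [O2]_0 * (1 - dP/P)^i`, and the coefficient deviations equal
#' `rel * |a|` and `rel * |b|` exactly.
#'
#' @param protocol A [baps_protocol()].
#' @param rel_gas_error Relative accuracy of the calibration gases
#'   (e.g. `0.02`).
#' @param truth Optional named list of true calibrations (`o2`, `co2`;
#'   [polynomial_calibration()] or fits) used to map nominal
#'   concentrations to sensor signals for the coefficient refit. Defaults
#'   to [default_sensor_truths()].
#'
#' @return A list of class `gas_error_scenario` with elements `per_step`
#'   (tibble: `step`, `dev_o2_volpct`, `dev_co2_volpct`,
#'   `dev_co2_umol_ml`), `coefficients` (tibble: `sensor`, `da`, `db`)
#'   and `rel_gas_error`.
#' @export
propagate_gas_error <- function(protocol, rel_gas_error = 0.02, truth = NULL) {
  stopifnot(inherits(protocol, "baps_protocol"))
  check_number(rel_gas_error, "rel_gas_error", nonneg = TRUE)
  if (is.null(truth)) truth <- default_sensor_truths()
  nominal <- run_protocol(protocol)

  perturbed_runs <- purrr::map(c(-1, 1), function(s_init) {
    purrr::map(c(-1, 1), function(s_inj) {
      init <- protocol$initial
      inj <- protocol$injected
      o2p <- init$frac_o2 * (1 + s_init * rel_gas_error)
      co2p <- inj$frac_co2 * (1 + s_inj * rel_gas_error)
      pert <- baps_protocol(
        initial = gas_mixture(o2p, init$frac_co2, 1 - o2p - init$frac_co2,
                              rel_accuracy = init$rel_accuracy),
        injected = gas_mixture(inj$frac_o2, co2p, 1 - inj$frac_o2 - co2p,
                               rel_accuracy = inj$rel_accuracy),
        n_steps = protocol$n_steps, dp_pa = protocol$dp_pa,
        p_pa = protocol$chamber$p_pa, t_k = protocol$chamber$t_k,
        v_head_ml = protocol$chamber$v_head_ml)
      run_protocol(pert)
    })
  })
  perturbed_runs <- purrr::flatten(perturbed_runs)

  env <- function(col) {
    devs <- purrr::map(perturbed_runs, function(r) abs(r[[col]] - nominal[[col]]))
    do.call(pmax, devs)
  }
  per_step <- tibble(
    step = nominal$step,
    dev_o2_volpct = env("o2_volpct"),
    dev_co2_volpct = env("co2_volpct"),
    dev_co2_umol_ml = env("co2_umol_ml")
  )

  ## coefficient deviations: refit perturbed measurands against the
  ## signals implied by the nominal concentrations and the true response
  coef_dev <- purrr::map_dfr(c("o2", "co2"), function(sensor) {
    cal <- as_polynomial_calibration(truth[[sensor]])
    col <- if (sensor == "o2") "o2_volpct" else "co2_umol_ml"
    x <- (nominal[[col]] - cal$a) / cal$b
    base <- fit_ols(calibration_data(nominal$step + 1L, x, nominal[[col]],
                                     sensor_kind = sensor))
    devs <- purrr::map_dfr(perturbed_runs, function(r) {
      f <- fit_ols(calibration_data(nominal$step + 1L, x, r[[col]],
                                    sensor_kind = sensor))
      tibble(da = abs(f$a - base$a), db = abs(f$b - base$b))
    })
    tibble(sensor = sensor, da = max(devs$da), db = max(devs$db))
  })

  structure(
    list(per_step = per_step, coefficients = coef_dev,
         rel_gas_error = rel_gas_error),
    class = "gas_error_scenario"
  )
}

#' @export
print.gas_error_scenario <- function(x, ...) {
  cat(sprintf("<gas_error_scenario> relative gas error %.1f%%\n",
              100 * x$rel_gas_error))
  cat(sprintf("  initial O2 deviation %.3f Vol%%; final %.3f Vol%% (step %d)\n",
              x$per_step$dev_o2_volpct[1],
              tail(x$per_step$dev_o2_volpct, 1),
              tail(x$per_step$step, 1)))
  print(x$coefficients)
  invisible(x)
}

#' Monte Carlo errors of the calibration coefficients
#'
#' Propagates the random input errors of the gas-exchange protocol all
#' the way to the calibration coefficients: each simulated run produces a
#' perturbed set of reference concentrations, which is refit by OLS
#' against the nominal sensor signals; the empirical standard deviations
#' of the refitted `a` and `b` across runs quantify the impact of `me_y`
#' on the calibration.
#'
#' @inheritParams mc_concentration_errors
#' @param truth Optional named list of true calibrations (`o2`, `co2`)
#'   used to map nominal concentrations to signals; defaults to
#'   [default_sensor_truths()].
#'
#' @return A tibble with columns `sensor`, `sd_a`, `sd_b`.
#' @export
mc_coefficient_errors <- function(protocol, spec = mc_input_spec(),
                                  truth = NULL) {
  stopifnot(inherits(protocol, "baps_protocol"), inherits(spec, "mc_input_spec"))
  if (spec$n_sim < 2) {
    stop_domain("need n_sim >= 2 to estimate coefficient standard deviations.")
  }
  if (is.null(truth)) truth <- default_sensor_truths()
  nominal <- run_protocol(protocol)
  runs <- mc_protocol_runs(protocol, spec)
  purrr::map_dfr(c("o2", "co2"), function(sensor) {
    cal <- as_polynomial_calibration(truth[[sensor]])
    col <- if (sensor == "o2") "o2_volpct" else "co2_umol_ml"
    x <- (nominal[[col]] - cal$a) / cal$b
    coefs <- purrr::map_dfr(runs, function(r) {
      f <- fit_ols(calibration_data(nominal$step + 1L, x, r[[col]],
                                    sensor_kind = sensor))
      tibble(a = f$a, b = f$b)
    })
    tibble(sensor = sensor, sd_a = sd(coefs$a), sd_b = sd(coefs$b))
  })
}
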