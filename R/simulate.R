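## Synthetic-data generator: simulated calibration runs (true linear
## sensor responses + noise + measurand errors), coefficient histories
## with controlled drift, and forward-simulated incubations with known
## turnover rates. One explicitly seeded base-R RNG stream per call
## (Mersenne-Twister via set.seed); fixed seed => bit-identical output.

#' Generative truth for one sensor
#'
#' The "true" calibration underlying simulated data: intercept, slope, an
#' optional mild quadratic term (to exercise the linearity diagnostics,
#' default off), the signal noise level, and per-year relative drifts of
#' the coefficients.
#'
#' @param a,b True calibration coefficients.
#' @param nonlin_c Optional quadratic coefficient of the true response.
#' @param me_x_v Signal noise s.d. (V).
#' @param residual_sd S.d. of the irreducible measurand scatter around
#'   the calibration line (the "individual part").
#' @param drift_a,drift_b Relative per-year drifts of `a` and `b`.
#'
#' @return An object of class `sensor_truth`.
#' @export
sensor_truth <- function(a, b, nonlin_c = 0, me_x_v = 0, residual_sd = 0,
                         drift_a = 0, drift_b = 0) {
  check_number(a, "a"); check_number(b, "b"); check_number(nonlin_c, "nonlin_c")
  check_number(me_x_v, "me_x_v", nonneg = TRUE)
  check_number(residual_sd, "residual_sd", nonneg = TRUE)
  check_number(drift_a, "drift_a"); check_number(drift_b, "drift_b")
  structure(
    list(a = a, b = b, nonlin_c = nonlin_c, me_x_v = me_x_v,
         residual_sd = residual_sd, drift_a = drift_a, drift_b = drift_b),
    class = c("sensor_truth", "polynomial_calibration")
  )
}

#' Default sensor truths
#'
#' Realistic generative calibrations for the three BaPS sensors: pressure
#' (hPa), O2 (Vol%) and CO2 (umol mL-1), with typical on-site noise
#' levels (0.2 mV pressure, 0.15 mV O2, 7 mV CO2) and residual scatter
#' matching well-maintained instruments.
#'
#' @return Named list of [sensor_truth()] objects (`pressure`, `o2`,
#'   `co2`).
#' @export
default_sensor_truths <- function() {
  list(
    pressure = sensor_truth(a = 699.6, b = 250.1, me_x_v = 2e-4,
                            residual_sd = sqrt(0.154)),
    o2 = sensor_truth(a = -3.69, b = 14.83, me_x_v = 1.5e-4,
                      residual_sd = sqrt(116e-6)),
    co2 = sensor_truth(a = -0.015, b = 0.52, me_x_v = 7e-3,
                       residual_sd = sqrt(10e-6))
  )
}

## invert the (possibly mildly quadratic) true response: signal for a
## given measurand, taking the root nearest the linear solution
invert_truth <- function(truth, y) {
  x_lin <- (y - truth$a) / truth$b
  if (truth$nonlin_c == 0) return(x_lin)
  vapply(y, function(yy) {
    roots <- polyroot(c(truth$a - yy, truth$b, truth$nonlin_c))
    roots <- Re(roots[abs(Im(roots)) < 1e-8])
    roots[which.min(abs(roots - (yy - truth$a) / truth$b))]
  }, numeric(1))
}

#' Default pressure-calibration point set
#'
#' Reference pressure levels for a simulated pressure calibration: nine
#' absolute pressures centred on ambient (1013.25 hPa), equally spaced
#' so that the mean absolute pressure difference from ambient across the
#' protocol is 26 hPa (the spacing is 26 * 9/20 = 11.7 hPa, spanning
#' roughly +/- 47 hPa around ambient).
#'
#' @param ambient_hpa Ambient pressure (hPa).
#' @return Numeric vector of 9 pressure levels (hPa).
#' @export
pressure_calibration_levels <- function(ambient_hpa = 1013.25) {
  ambient_hpa + 11.7 * (-4:4)
}

#' Simulate a full calibration run
#'
#' Forward-simulates the on-site calibration of all three sensors: the
#' reference O2 and CO2 concentrations are computed from the gas-exchange
#' protocol through the mole balance, the pressure references from a
#' stepwise pressure manipulation; the true calibration of each sensor is
#' inverted to obtain the true signals; replicated readings add
#' `N(0, me_x)` signal noise; the recorded measurand adds `N(0,
#' residual_sd)` scatter plus `N(0, me_y)` reference error.
#'
#' @param truths Named list of [sensor_truth()] objects (`pressure`,
#'   `o2`, `co2`); default [default_sensor_truths()].
#' @param protocol A [baps_protocol()] for the gas sensors.
#' @param pressure_levels_hpa Pressure reference levels (hPa) for the
#'   pressure calibration.
#' @param replicates Signal readings per calibration point.
#' @param me_y Named numeric: reference-value error s.d. per sensor
#'   (pressure hPa, o2 Vol%, co2 umol mL-1).
#' @param seed RNG seed (optional; fixed seed gives bit-identical
#'   output).
#'
#' @return A list with `datasets` (named list of [calibration_data()]
#'   tibbles per sensor) and `log` (a long signal-log tibble with
#'   `timestamp`, `sensor_id`, `signal_v`).
#' @export
simulate_calibration_run <- function(truths = default_sensor_truths(),
                                     protocol = baps_protocol(),
                                     pressure_levels_hpa = pressure_calibration_levels(),
                                     replicates = 10,
                                     me_y = c(pressure = 0.052, o2 = 0.0033,
                                              co2 = 0.0013),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("pressure", "o2", "co2") %in% names(truths)))
  if (replicates < 1) stop_domain("replicates must be >= 1.")
  ref <- run_protocol(protocol)
  targets <- list(
    pressure = pressure_levels_hpa,
    o2 = ref$o2_volpct,
    co2 = ref$co2_umol_ml
  )
  datasets <- purrr::imap(targets, function(y_true, sensor) {
    truth <- truths[[sensor]]
    k <- length(y_true)
    x_true <- invert_truth(truth, y_true)
    y_obs <- y_true + rnorm(k, 0, truth$residual_sd) +
      rnorm(k, 0, me_y[[sensor]])
    z <- rep(x_true, each = replicates) +
      rnorm(k * replicates, 0, truth$me_x_v)
    calibration_data(
      point_id = rep(seq_len(k), each = replicates),
      signal_v = z,
      measurand = rep(y_obs, each = replicates),
      me_y = me_y[[sensor]],
      sensor_kind = if (sensor == "pressure") "pressure" else sensor
    )
  })
  log <- purrr::imap_dfr(datasets, function(d, sensor) {
    tibble(
      timestamp = format(
        as.POSIXct("2015-07-01 08:00:00", tz = "UTC") +
          60 * seq_len(nrow(d)), "%Y-%m-%dT%H:%M:%S"),
      sensor_id = sensor,
      signal_v = d$signal_v
    )
  })
  list(datasets = datasets, log = log)
}

#' Simulate a dated calibration-coefficient history
#'
#' Applies linear per-year relative drifts plus between-calibration
#' scatter to a sensor's true coefficients, at a fixed number of
#' calibrations per year.
#'
#' @param truth A [sensor_truth()] (its `drift_a` / `drift_b` are used).
#' @param n_years Span of the history in years.
#' @param per_year Calibrations per year.
#' @param scatter_a,scatter_b Between-calibration s.d. of the
#'   coefficients.
#' @param start_date First calibration date.
#' @param seed RNG seed (optional).
#'
#' @return A tibble with columns `date`, `a`, `b`.
#' @export
simulate_coefficient_history <- function(truth, n_years = 4, per_year = 2,
                                         scatter_a = 0, scatter_b = 0,
                                         start_date = as.Date("2012-05-01"),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "sensor_truth"))
  n <- round(n_years * per_year)
  if (n < 2) stop_data("history needs at least 2 entries.")
  years <- (seq_len(n) - 1) / per_year
  tibble(
    date = start_date + round(365.25 * years),
    a = truth$a * (1 + truth$drift_a * years) + rnorm(n, 0, scatter_a),
    b = truth$b * (1 + truth$drift_b * years) + rnorm(n, 0, scatter_b)
  )
}

#' Forward-simulate a BaPS incubation with known turnover rates
#'
#' Integrates the chamber gas balance implied by constant respiration and
#' gross nitrification rates: CO2 is produced at the respiration rate and
#' partitioned between headspace and the dissolved pool (which tracks the
#' CO2 mole fraction linearly), O2 is consumed by respiration (via RQ)
#' and nitrification (via the O2:N stoichiometry), and pressure follows
#' from the ideal gas law. The true state is then converted to sensor
#' signals through the true calibrations and signal noise is added.
#'
#' @param respiration True respiration rate (ugC kg-1 sdw h-1).
#' @param nitrification True gross nitrification rate (ugN kg-1 sdw h-1).
#' @param soil A [soil_params()] object.
#' @param truths Named list of [sensor_truth()] objects.
#' @param duration_h Incubation length (h).
#' @param dt_out_h Output sampling interval (h).
#' @param p0_hpa,t_k,v_head_ml Initial chamber pressure (hPa),
#'   temperature (K) and headspace volume (mL).
#' @param initial Initial headspace composition ([gas_mixture()]);
#'   default ambient air (20.9% O2, 0.04% CO2).
#' @param noise Add sensor signal noise?
#' @param extra_x_rate Net production rate of gases other than O2/CO2
#'   (umol h-1), entering `delta_x` (default 0).
#' @param seed RNG seed (optional).
#'
#' @return A tibble with `timestamp_h`, raw signals (`signal_p_v`,
#'   `signal_o2_v`, `signal_co2_v`), temperatures (`t_head_k`,
#'   `t_soil_k`) and the true measurands (`p_hpa`, `o2_volpct`,
#'   `co2_umol_ml`); `v_head_ml` and `soil` are attached as attributes.
#'   A warning is issued when the CO2 concentration leaves the sensor's
#'   0-3 Vol% measuring range.
#' @export
simulate_incubation <- function(respiration, nitrification,
                                soil = soil_params(),
                                truths = default_sensor_truths(),
                                duration_h = 12, dt_out_h = 0.25,
                                p0_hpa = 1013.25, t_k = 293.15,
                                v_head_ml = 1000,
                                initial = gas_mixture(0.209, 0.0004),
                                noise = TRUE, extra_x_rate = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_number(respiration, "respiration")
  check_number(nitrification, "nitrification")
  check_number(duration_h, "duration_h", positive = TRUE)
  check_number(dt_out_h, "dt_out_h", positive = TRUE)
  stopifnot(inherits(soil, "soil_params"))

  v_m3 <- v_head_ml * 1e-6
  n0 <- moles_from_state(p0_hpa * 100, v_m3, t_k) * 1e6 # umol
  n_o2 <- n0 * initial$frac_o2
  n_co2 <- n0 * initial$frac_co2
  n_n2 <- n0 * initial$frac_n2

  ## constant molar rates implied by the specific rates, umol h^-1
  co2_prod <- respiration * soil$soil_dry_weight_kg / M_CARBON
  nit_o2 <- nitrification * soil$soil_dry_weight_kg / M_NITROGEN *
    soil$nitrification_o2_stoich
  o2_cons <- co2_prod / soil$rq + nit_o2
  d_pool <- dissolved_pool_scale(soil)

  dt <- 0.005
  times_out <- seq(0, duration_h, by = dt_out_h)
  n_sub <- max(1L, round(dt_out_h / dt))
  dt <- dt_out_h / n_sub

  rows <- vector("list", length(times_out))
  record <- function(i) {
    n_tot <- n_o2 + n_co2 + n_n2
    rows[[i]] <<- tibble(
      timestamp_h = times_out[i],
      p_hpa = n_tot * 1e-6 * R_GAS * t_k / v_m3 / 100,
      o2_volpct = 100 * n_o2 / n_tot,
      co2_umol_ml = n_co2 / v_head_ml,
      t_head_k = t_k, t_soil_k = t_k
    )
  }
  record(1L)
  for (i in seq_along(times_out)[-1]) {
    for (s in seq_len(n_sub)) {
      n_tot <- n_o2 + n_co2 + n_n2
      x <- n_co2 / n_tot
      dC <- co2_prod * dt
      dO <- o2_cons * dt
      dX <- extra_x_rate * dt
      ## CO2 split between headspace and dissolved pool such that the
      ## dissolved amount stays at d_pool * x (linear equilibrium)
      dg <- (dC - d_pool * x * (dO - dX) / n_tot) /
        (1 + d_pool * (1 - x) / n_tot)
      n_co2 <- n_co2 + dg
      n_o2 <- n_o2 - dO
      n_n2 <- n_n2 + dX
      if (n_o2 < 0) stop_infeasible("O2 pool exhausted during simulation.")
    }
    record(i)
  }
  out <- dplyr::bind_rows(rows)

  co2_volpct <- umol_per_ml_to_volpct(out$co2_umol_ml, out$p_hpa * 100, t_k)
  if (any(co2_volpct > 3)) {
    warn("simulated CO2 concentration exceeds the sensor's 3 Vol% measuring range; readings would be truncated on the instrument.")
  }

  noise_sd <- function(sensor) if (noise) truths[[sensor]]$me_x_v else 0
  out <- dplyr::mutate(
    out,
    signal_p_v = invert_truth(truths$pressure, .data$p_hpa) +
      rnorm(dplyr::n(), 0, noise_sd("pressure")),
    signal_o2_v = invert_truth(truths$o2, .data$o2_volpct) +
      rnorm(dplyr::n(), 0, noise_sd("o2")),
    signal_co2_v = invert_truth(truths$co2, .data$co2_umol_ml) +
      rnorm(dplyr::n(), 0, noise_sd("co2"))
  )
  out <- dplyr::relocate(out, "timestamp_h", "signal_p_v", "signal_o2_v",
                         "signal_co2_v", "t_head_k", "t_soil_k")
  attr(out, "v_head_ml") <- v_head_ml
  attr(out, "soil") <- soil
  out
}
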