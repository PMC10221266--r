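## Ideal-gas mole-balance engine for the stepwise O2/CO2 calibration
## protocol: removal/injection cycles, headspace volume determination and
## unit conversions. Internal units are SI (Pa, m3, K, mol); hPa, mL, Vol%
## and umol mL^-1 appear only at the I/O boundary.

#' Gas mixture by volume fractions
#'
#' Describes a (calibration) gas as volume fractions of O2, CO2 and N2,
#' together with the relative concentration accuracy stated by the gas
#' supplier. Fractions must sum to one.
#'
#' @param frac_o2,frac_co2,frac_n2 Volume fractions in `[0, 1]`
#'   (Vol% / 100). If `frac_n2` is `NULL` it is set to the remainder.
#' @param rel_accuracy Relative concentration accuracy of the mixture
#'   (dimensionless, e.g. `0.02` for the typical 2% filler tolerance).
#'
#' @return An object of class `gas_mixture`.
#' @examples
#' synthetic_air()
#' gas_mixture(frac_o2 = 0, frac_co2 = 0.205)
#' @export
gas_mixture <- function(frac_o2, frac_co2, frac_n2 = NULL, rel_accuracy = 0.02) {
  check_number(frac_o2, "frac_o2", nonneg = TRUE)
  check_number(frac_co2, "frac_co2", nonneg = TRUE)
  if (is.null(frac_n2)) frac_n2 <- 1 - frac_o2 - frac_co2
  check_number(frac_n2, "frac_n2", nonneg = TRUE)
  check_number(rel_accuracy, "rel_accuracy", nonneg = TRUE)
  if (abs(frac_o2 + frac_co2 + frac_n2 - 1) > 1e-9) {
    stop_domain("gas mixture fractions must sum to 1 (within 1e-9).")
  }
  structure(
    list(frac_o2 = frac_o2, frac_co2 = frac_co2, frac_n2 = frac_n2,
         rel_accuracy = rel_accuracy),
    class = "gas_mixture"
  )
}

#' @rdname gas_mixture
#' @export
synthetic_air <- function(rel_accuracy = 0.02) {
  gas_mixture(frac_o2 = 0.205, frac_co2 = 0, frac_n2 = 0.795,
              rel_accuracy = rel_accuracy)
}

#' @rdname gas_mixture
#' @export
co2_calibration_gas <- function(rel_accuracy = 0.02) {
  gas_mixture(frac_o2 = 0, frac_co2 = 0.205, frac_n2 = 0.795,
              rel_accuracy = rel_accuracy)
}

#' @export
print.gas_mixture <- function(x, ...) {
  cat(sprintf("<gas_mixture> O2 %.3f | CO2 %.3f | N2 %.3f (rel. accuracy %.1f%%)\n",
              x$frac_o2, x$frac_co2, x$frac_n2, 100 * x$rel_accuracy))
  invisible(x)
}

#' Headspace gas state
#'
#' Amount-of-substance bookkeeping for the chamber headspace: total moles,
#' species moles, pressure, temperature and headspace volume. The total is
#' tied to `P * V / (R * T)` by the ideal gas law and the species amounts
#' must sum to the total.
#'
#' @param p_pa Absolute pressure (Pa).
#' @param t_k Temperature (K).
#' @param v_head_m3 Headspace volume (m3).
#' @param mixture A [gas_mixture()] giving the species composition.
#'
#' @return An object of class `gas_state` with fields `n_total`, `n_o2`,
#'   `n_co2`, `n_n2` (mol), `p_pa`, `t_k`, `v_head_m3`.
#' @examples
#' gas_state(101325, 293.15, 1e-3, synthetic_air())
#' @export
gas_state <- function(p_pa, t_k, v_head_m3, mixture = synthetic_air()) {
  check_number(p_pa, "p_pa", positive = TRUE)
  check_number(t_k, "t_k", positive = TRUE)
  check_number(v_head_m3, "v_head_m3", positive = TRUE)
  stopifnot(inherits(mixture, "gas_mixture"))
  n <- moles_from_state(p_pa, v_head_m3, t_k)
  new_gas_state(n * mixture$frac_o2, n * mixture$frac_co2, n * mixture$frac_n2,
                t_k, v_head_m3)
}

## internal constructor: recomputes P from the ideal gas law so that the
## state invariants hold by construction
new_gas_state <- function(n_o2, n_co2, n_n2, t_k, v_head_m3) {
  n <- n_o2 + n_co2 + n_n2
  structure(
    list(n_total = n, n_o2 = n_o2, n_co2 = n_co2, n_n2 = n_n2,
         p_pa = n * R_GAS * t_k / v_head_m3, t_k = t_k, v_head_m3 = v_head_m3),
    class = "gas_state"
  )
}

#' @export
print.gas_state <- function(x, ...) {
  cat(sprintf(
    "<gas_state> n = %.5f mol | O2 %.3f Vol%% | CO2 %.3f Vol%% | N2 %.3f Vol%%\n",
    x$n_total, 100 * x$n_o2 / x$n_total, 100 * x$n_co2 / x$n_total,
    100 * x$n_n2 / x$n_total))
  cat(sprintf("  P = %.2f hPa | T = %.2f K | V_head = %.1f mL\n",
              x$p_pa / 100, x$t_k, x$v_head_m3 * 1e6))
  invisible(x)
}

#' One gas removal/injection exchange
#'
#' A calibration exchange: a gas volume is withdrawn with a gastight
#' syringe (pressure drop `dp_out_pa`) and replaced by calibration gas
#' (pressure rise `dp_in_pa`). Both pressure differences are signed
#' magnitudes (non-negative); direction is carried by the operation.
#'
#' @param dp_out_pa Pressure drop after gas removal (Pa, >= 0).
#' @param dp_in_pa Pressure rise after injection (Pa, >= 0).
#' @param injected [gas_mixture()] injected after removal.
#' @param t_out_k,t_in_k Headspace temperatures during removal and
#'   injection (K); default both equal `t_k` of the state they are
#'   applied to when `NA`.
#'
#' @return An object of class `exchange_step`.
#' @export
exchange_step <- function(dp_out_pa, dp_in_pa, injected = co2_calibration_gas(),
                          t_out_k = NA_real_, t_in_k = NA_real_) {
  check_number(dp_out_pa, "dp_out_pa", nonneg = TRUE)
  check_number(dp_in_pa, "dp_in_pa", nonneg = TRUE)
  if (!is.na(t_out_k)) check_number(t_out_k, "t_out_k", positive = TRUE)
  if (!is.na(t_in_k)) check_number(t_in_k, "t_in_k", positive = TRUE)
  stopifnot(inherits(injected, "gas_mixture"))
  structure(
    list(dp_out_pa = dp_out_pa, dp_in_pa = dp_in_pa, injected = injected,
         t_out_k = t_out_k, t_in_k = t_in_k),
    class = "exchange_step"
  )
}

#' Amount of gas from the ideal gas law
#'
#' @param p_pa Pressure (Pa, > 0).
#' @param v_m3 Volume (m3, >= 0; zero volume holds zero gas).
#' @param t_k Temperature (K, > 0).
#'
#' @return Amount of substance (mol), `p_pa * v_m3 / (R * t_k)` with
#'   `R = 8.314` Pa m3 K-1 mol-1.
#' @examples
#' moles_from_state(101325, 0.001, 298.15)
#' @export
moles_from_state <- function(p_pa, v_m3, t_k) {
  check_number(p_pa, "p_pa", positive = TRUE)
  check_number(t_k, "t_k", positive = TRUE)
  check_number(v_m3, "v_m3", nonneg = TRUE)
  p_pa * v_m3 / (R_GAS * t_k)
}

#' Apply a removal/injection exchange to a headspace state
#'
#' Removes `dp_out * V_head / (R * T_out)` moles proportionally to the
#' current species fractions (well-mixed headspace), then adds
#' `dp_in * V_head / (R * T_in)` moles with the injected mixture's
#' composition. The pressure of the returned state is recomputed from the
#' ideal gas law.
#'
#' @param state A [gas_state()].
#' @param step An [exchange_step()].
#'
#' @return The updated [gas_state()].
#' @examples
#' s0 <- gas_state(100000, 293.15, 1e-3, synthetic_air())
#' apply_exchange(s0, exchange_step(1000, 1000))
#' @export
apply_exchange <- function(state, step) {
  stopifnot(inherits(state, "gas_state"), inherits(step, "exchange_step"))
  t_out <- if (is.na(step$t_out_k)) state$t_k else step$t_out_k
  t_in <- if (is.na(step$t_in_k)) state$t_k else step$t_in_k
  n_out <- step$dp_out_pa * state$v_head_m3 / (R_GAS * t_out)
  if (n_out > state$n_total + 1e-15) {
    stop_infeasible(sprintf(
      "removal of %.4g mol exceeds the headspace pool of %.4g mol.",
      n_out, state$n_total))
  }
  frac_out <- if (state$n_total > 0) n_out / state$n_total else 0
  n_in <- step$dp_in_pa * state$v_head_m3 / (R_GAS * t_in)
  inj <- step$injected
  new_gas_state(
    n_o2 = state$n_o2 * (1 - frac_out) + n_in * inj$frac_o2,
    n_co2 = state$n_co2 * (1 - frac_out) + n_in * inj$frac_co2,
    n_n2 = state$n_n2 * (1 - frac_out) + n_in * inj$frac_n2,
    t_k = state$t_k, v_head_m3 = state$v_head_m3
  )
}

#' Stepwise gas-exchange calibration protocol
#'
#' The standard on-site O2/CO2 calibration protocol: the headspace starts
#' filled with synthetic air and a fixed gas volume is repeatedly removed
#' and replaced by a CO2/N2 mixture, stepping O2 down and CO2 up through
#' the sensors' measuring ranges while total pressure and N2 stay constant.
#'
#' The default emulates a typical chamber (1013.25 hPa, 293.15 K, 1000 mL
#' headspace) with 8 exchanges of 2% of the headspace amount each, which
#' walks O2 from 20.5 down to about 17.5 Vol% and CO2 from 0 up to about
#' 3 Vol% — the instrument's relevant measuring ranges.
#'
#' @param initial,injected [gas_mixture()] objects: the starting fill and
#'   the injected calibration gas.
#' @param n_steps Number of removal/injection exchanges.
#' @param dp_pa Pressure drop = rise per exchange (Pa). Alternatively give
#'   `removal_volume_ml` and the equivalent isobaric `dp_pa` is derived as
#'   `P * removal_volume_ml / V_head_ml`.
#' @param removal_volume_ml Optional syringe volume per exchange (mL).
#' @param p_pa,t_k,v_head_ml Chamber pressure (Pa), temperature (K) and
#'   headspace volume (mL).
#'
#' @return An object of class `baps_protocol`.
#' @seealso [run_protocol()], [idealized_concentrations()]
#' @export
baps_protocol <- function(initial = synthetic_air(),
                          injected = co2_calibration_gas(),
                          n_steps = 8,
                          dp_pa = NULL,
                          removal_volume_ml = NULL,
                          p_pa = 101325, t_k = 293.15, v_head_ml = 1000) {
  check_number(p_pa, "p_pa", positive = TRUE)
  check_number(t_k, "t_k", positive = TRUE)
  check_number(v_head_ml, "v_head_ml", positive = TRUE)
  if (is.null(dp_pa)) {
    if (is.null(removal_volume_ml)) removal_volume_ml <- 0.02 * v_head_ml
    check_number(removal_volume_ml, "removal_volume_ml", positive = TRUE)
    dp_pa <- p_pa * removal_volume_ml / v_head_ml
  }
  check_number(dp_pa, "dp_pa", nonneg = TRUE)
  if (dp_pa >= p_pa) stop_domain("dp_pa must be smaller than the chamber pressure.")
  stopifnot(inherits(initial, "gas_mixture"), inherits(injected, "gas_mixture"))
  if (n_steps < 0 || n_steps != round(n_steps)) {
    stop_domain("n_steps must be a non-negative integer.")
  }
  structure(
    list(initial = initial, injected = injected, n_steps = as.integer(n_steps),
         dp_pa = dp_pa, chamber = list(p_pa = p_pa, t_k = t_k,
                                       v_head_ml = v_head_ml)),
    class = "baps_protocol"
  )
}

#' @export
print.baps_protocol <- function(x, ...) {
  cat(sprintf(
    "<baps_protocol> %d exchanges of dP = %.1f hPa at P = %.1f hPa, T = %.2f K, V_head = %.0f mL\n",
    x$n_steps, x$dp_pa / 100, x$chamber$p_pa / 100, x$chamber$t_k,
    x$chamber$v_head_ml))
  invisible(x)
}

#' Run an exchange protocol through the mole balance
#'
#' Executes the removal/injection cycles of a [baps_protocol()] step by
#' step through [apply_exchange()] and reports the reference headspace
#' composition at every calibration step (step 0 is the initial fill).
#'
#' @param protocol A [baps_protocol()].
#' @param dp_out_pa,dp_in_pa,t_out_k,t_in_k Optional per-step overrides
#'   (vectors of length `n_steps`) for the removal/injection pressure
#'   differences and temperatures; defaults use the protocol's `dp_pa` and
#'   the chamber temperature throughout (the idealized conditions).
#'
#' @return A tibble with one row per step: `step`, `o2_volpct`,
#'   `co2_volpct`, `n2_volpct`, `co2_umol_ml`, `n_total_mol`, `p_hpa`.
#' @examples
#' run_protocol(baps_protocol(n_steps = 3))
#' @export
run_protocol <- function(protocol, dp_out_pa = NULL, dp_in_pa = NULL,
                         t_out_k = NULL, t_in_k = NULL) {
  stopifnot(inherits(protocol, "baps_protocol"))
  ch <- protocol$chamber
  n_steps <- protocol$n_steps
  rep_or <- function(x, default) if (is.null(x)) rep(default, n_steps) else rep_len(x, n_steps)
  dp_out_pa <- rep_or(dp_out_pa, protocol$dp_pa)
  dp_in_pa <- rep_or(dp_in_pa, protocol$dp_pa)
  t_out_k <- rep_or(t_out_k, ch$t_k)
  t_in_k <- rep_or(t_in_k, ch$t_k)

  state <- gas_state(ch$p_pa, ch$t_k, ch$v_head_ml * 1e-6, protocol$initial)
  states <- vector("list", n_steps + 1L)
  states[[1L]] <- state
  for (i in seq_len(n_steps)) {
    state <- apply_exchange(state, exchange_step(
      dp_out_pa[i], dp_in_pa[i], injected = protocol$injected,
      t_out_k = t_out_k[i], t_in_k = t_in_k[i]))
    states[[i + 1L]] <- state
  }
  purrr::map2_dfr(states, seq_along(states) - 1L, function(s, i) {
    tibble(
      step = i,
      o2_volpct = 100 * s$n_o2 / s$n_total,
      co2_volpct = 100 * s$n_co2 / s$n_total,
      n2_volpct = 100 * s$n_n2 / s$n_total,
      co2_umol_ml = s$n_co2 / s$v_head_m3, # mol m-3 == umol mL-1
      n_total_mol = s$n_total,
      p_hpa = s$p_pa / 100
    )
  })
}

#' Closed-form concentrations under idealized exchange conditions
#'
#' Under constant temperature and equal removal/injection pressure
#' differences (`dP_out = dP_in = dP`, constant `P`), the stepwise mole
#' balance collapses to a geometric recursion: each exchange multiplies
#' every deviation from the injected composition by `(1 - dP/P)`. O2
#' decays as `[O2]_i = [O2]_0 (1 - dP/P)^i`; CO2 relaxes towards the
#' injected concentration analogously.
#'
#' @param i Number of exchanges performed (non-negative integer,
#'   vectorized).
#' @param dp_pa Pressure increment per exchange (Pa, `0 <= dP < P`).
#' @param p_pa Chamber pressure (Pa).
#' @param initial,injected [gas_mixture()] objects.
#'
#' @return A tibble with columns `step`, `o2_volpct`, `co2_volpct`,
#'   `n2_volpct` (fractions sum to 100 Vol%).
#' @examples
#' idealized_concentrations(0:3, dp_pa = 1000, p_pa = 100000)
#' @export
idealized_concentrations <- function(i, dp_pa, p_pa,
                                     initial = synthetic_air(),
                                     injected = co2_calibration_gas()) {
  check_number(dp_pa, "dp_pa", nonneg = TRUE)
  check_number(p_pa, "p_pa", positive = TRUE)
  if (dp_pa >= p_pa) stop_domain("dp_pa must be smaller than p_pa.")
  if (any(i < 0) || any(i != round(i))) {
    stop_domain("`i` must contain non-negative integers.")
  }
  q <- dp_pa / p_pa
  decay <- (1 - q)^i
  relax <- function(c0, cinj) 100 * (cinj + (c0 - cinj) * decay)
  tibble(
    step = as.integer(i),
    o2_volpct = relax(initial$frac_o2, injected$frac_o2),
    co2_volpct = relax(initial$frac_co2, injected$frac_co2),
    n2_volpct = relax(initial$frac_n2, injected$frac_n2)
  )
}

#' Convert between Vol% and umol per mL
#'
#' At pressure `P` and temperature `T`, a volume fraction `c` (Vol%)
#' corresponds to a molar concentration `(c/100) * P / (R * T)`; with SI
#' inputs the value of `P/(R T)` in mol m-3 is numerically the
#' concentration of the pure gas in umol mL-1.
#'
#' @param c_volpct Concentration in Vol%.
#' @param c_umol_ml Concentration in umol mL-1.
#' @param p_pa Pressure (Pa).
#' @param t_k Temperature (K).
#'
#' @return Numeric concentration in the target unit.
#' @examples
#' volpct_to_umol_per_ml(100, 100000, 293.15)
#' @export
volpct_to_umol_per_ml <- function(c_volpct, p_pa, t_k) {
  check_number(p_pa, "p_pa", positive = TRUE)
  check_number(t_k, "t_k", positive = TRUE)
  (c_volpct / 100) * p_pa / (R_GAS * t_k)
}

#' @rdname volpct_to_umol_per_ml
#' @export
umol_per_ml_to_volpct <- function(c_umol_ml, p_pa, t_k) {
  check_number(p_pa, "p_pa", positive = TRUE)
  check_number(t_k, "t_k", positive = TRUE)
  100 * c_umol_ml * R_GAS * t_k / p_pa
}

#' Headspace volume from isothermal volume extension
#'
#' The chamber volume is determined by extending the closed headspace by a
#' known syringe volume `dV` and recording the pressure drop `dP`.
#' Isothermal expansion (Boyle's law, `P0 V = (P0 - dP)(V + dV)`) gives
#' `V_head = (P0 - dP) dV / dP`. Triplicate determinations are averaged
#' arithmetically.
#'
#' @param p0_pa Initial absolute pressure(s) (Pa).
#' @param dp_pa Pressure drop(s) after extension (Pa, `0 < dP < P0`).
#' @param dv_ml Extension volume(s) (mL, > 0).
#'
#' @return Mean headspace volume (mL).
#' @examples
#' headspace_volume(100000, c(1010, 1000, 990), 10)
#' @export
headspace_volume <- function(p0_pa, dp_pa, dv_ml) {
  check_number(p0_pa, "p0_pa", positive = TRUE)
  check_number(dv_ml, "dv_ml", positive = TRUE)
  check_number(dp_pa, "dp_pa", nonneg = TRUE)
  if (any(dp_pa <= 0)) {
    stop_infeasible("no measurable pressure drop: the headspace volume is unconstrained.")
  }
  if (any(dp_pa >= p0_pa)) {
    stop_domain("dp_pa must be smaller than p0_pa.")
  }
  mean((p0_pa - dp_pa) * dv_ml / dp_pa)
}

#' First-order uncertainty of the headspace volume
#'
#' Gaussian propagation of the two dominant relative error components of
#' the volume-extension measurement — the syringe volume tolerance and the
#' relative error of the pressure-change measurement (the relative
#' standard error of the pressure calibration slope) — through the
#' Boyle's-law formula. Both components act multiplicatively to first
#' order, so the absolute standard deviation is
#' `V_head * sqrt(syringe^2 + slope^2)`.
#'
#' @param syringe_rel_error Relative error of the syringe volume
#'   (dimensionless, e.g. `0.01`).
#' @param pressure_slope_rel_error Relative error of the pressure-change
#'   measurement (dimensionless, e.g. `0.0042`).
#' @param v_head_ml Headspace volume (mL).
#'
#' @return Standard deviation of `V_head` (mL).
#' @examples
#' vhead_uncertainty(0.01, 0.0042, 1000)
#' @export
vhead_uncertainty <- function(syringe_rel_error, pressure_slope_rel_error,
                              v_head_ml) {
  check_number(syringe_rel_error, "syringe_rel_error", nonneg = TRUE)
  check_number(pressure_slope_rel_error, "pressure_slope_rel_error", nonneg = TRUE)
  check_number(v_head_ml, "v_head_ml", positive = TRUE)
  v_head_ml * sqrt(syringe_rel_error^2 + pressure_slope_rel_error^2)
}
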