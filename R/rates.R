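## Simplified BaPS turnover-rate model. The instrument separates
## microbial respiration from gross nitrification by balancing total and
## partial pressure changes in the gastight chamber:
##   delta_n = delta_O2 + delta_CO2 + delta_X
## All CO2 production (gaseous + dissolved) is attributed to respiration;
## the O2 consumption implied by respiration (via the respiratory
## quotient RQ) is subtracted from the total O2 consumption, and the
## excess is attributed to nitrification through an explicit O2:N
## stoichiometry (default 2 mol O2 per mol N, NH4+ + 2 O2 -> NO3-).
## This is a documented simplification of the proprietary instrument
## algorithm; every assumption is a visible parameter.

M_CARBON <- 12.011   # g mol^-1
M_NITROGEN <- 14.007 # g mol^-1

#' Soil and model parameters for the turnover-rate model
#'
#' @param rq Respiratory quotient: mol CO2 produced per mol O2 consumed
#'   by respiration (default 0.84).
#' @param co2_dissolution_capacity_mmol_l CO2 uptake capacity of the soil
#'   solution (mmol per L solution at a pure-CO2 headspace; the dissolved
#'   pool scales linearly with the headspace CO2 mole fraction).
#' @param soil_solution_volume_l Volume of soil solution in the chamber (L).
#' @param soil_dry_weight_kg Soil dry weight (kg), used to normalise the
#'   rates.
#' @param nitrification_o2_stoich Mol O2 consumed per mol N nitrified
#'   (default 2).
#'
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(rq = 0.84, co2_dissolution_capacity_mmol_l = 0.33,
                        soil_solution_volume_l = 0.3,
                        soil_dry_weight_kg = 1.5,
                        nitrification_o2_stoich = 2) {
  check_number(rq, "rq", positive = TRUE)
  check_number(co2_dissolution_capacity_mmol_l,
               "co2_dissolution_capacity_mmol_l", nonneg = TRUE)
  check_number(soil_solution_volume_l, "soil_solution_volume_l", nonneg = TRUE)
  check_number(soil_dry_weight_kg, "soil_dry_weight_kg", positive = TRUE)
  check_number(nitrification_o2_stoich, "nitrification_o2_stoich",
               positive = TRUE)
  structure(
    list(rq = rq,
         co2_dissolution_capacity_mmol_l = co2_dissolution_capacity_mmol_l,
         soil_solution_volume_l = soil_solution_volume_l,
         soil_dry_weight_kg = soil_dry_weight_kg,
         nitrification_o2_stoich = nitrification_o2_stoich),
    class = "soil_params"
  )
}

## dissolved-pool scale: umol dissolved per unit CO2 mole fraction
dissolved_pool_scale <- function(soil) {
  soil$co2_dissolution_capacity_mmol_l * 1000 * soil$soil_solution_volume_l
}

check_series <- function(series) {
  need <- c("timestamp_h", "p_hpa", "t_head_k", "o2_volpct", "co2_umol_ml")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols)) {
    stop_data(paste0("incubation series lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (nrow(series) < 2) stop_data("incubation series needs >= 2 time points.")
  if (any(diff(series$timestamp_h) <= 0)) {
    stop_data("timestamps must be strictly increasing.")
  }
  invisible(series)
}

ols_slope <- function(t, y) {
  if (sd(y) == 0) return(0)
  unname(coef(lm(y ~ t))[2])
}

#' Gas-balance terms of an incubation series
#'
#' Converts a calibrated incubation time series into the molar change
#' rates of the chamber gas balance: the total amount `n` from `P`, `T`
#' and `V_head` via the ideal gas law, the O2 and gaseous CO2 amounts
#' from the measured concentrations, each regressed on time by OLS over
#' the analysis window. `delta_x = delta_n - delta_o2 - delta_co2` closes
#' the balance by construction.
#'
#' @param series Tibble with columns `timestamp_h`, `p_hpa`, `t_head_k`,
#'   `o2_volpct`, `co2_umol_ml` (as produced by [simulate_incubation()]
#'   or [read_incubation()]).
#' @param v_head_ml Headspace volume (mL); taken from the series
#'   attribute when missing.
#'
#' @return A tibble with `delta_n`, `delta_o2`, `delta_co2`, `delta_x`
#'   (umol h-1) and `x_co2_slope` (mole-fraction change per h, used for
#'   the dissolved-CO2 term).
#' @export
gas_balance_terms <- function(series, v_head_ml = NULL) {
  check_series(series)
  v_head_ml <- v_head_ml %||% attr(series, "v_head_ml", exact = TRUE)
  if (is.null(v_head_ml)) stop_data("v_head_ml must be given (or attached to the series).")
  v_m3 <- v_head_ml * 1e-6
  n_umol <- series$p_hpa * 100 * v_m3 / (R_GAS * series$t_head_k) * 1e6
  n_o2 <- n_umol * series$o2_volpct / 100
  n_co2 <- series$co2_umol_ml * v_head_ml
  t <- series$timestamp_h
  dn <- ols_slope(t, n_umol)
  do2 <- ols_slope(t, n_o2)
  dco2 <- ols_slope(t, n_co2)
  tibble(
    delta_n = dn, delta_o2 = do2, delta_co2 = dco2,
    delta_x = dn - do2 - dco2,
    x_co2_slope = ols_slope(t, n_co2 / n_umol)
  )
}

#' Respiration and gross nitrification from an incubation series
#'
#' Applies the simplified process-separation model: total CO2 production
#' is the gaseous CO2 change plus the change of the dissolved pool
#' (dissolution capacity x solution volume, tracking the headspace CO2
#' mole fraction linearly); respiratory O2 consumption is CO2 production
#' divided by RQ; the remaining O2 consumption is attributed to
#' nitrification and converted to an N oxidation rate through the O2:N
#' stoichiometry. Rates are normalised to soil dry weight.
#'
#' Negative computed rates are flagged (`negative_rate_flag`), never
#' clipped.
#'
#' @inheritParams gas_balance_terms
#' @param soil A [soil_params()] object.
#'
#' @return A tibble of class `rate_result` with `respiration`
#'   (ugC kg-1 sdw h-1), `gross_nitrification` (ugN kg-1 sdw h-1), the
#'   balance terms `delta_n`, `delta_o2`, `delta_co2`, `delta_x`,
#'   `delta_co2_aq` (umol h-1) and `negative_rate_flag`.
#' @export
turnover_rates <- function(series, soil = soil_params(), v_head_ml = NULL) {
  stopifnot(inherits(soil, "soil_params"))
  terms <- gas_balance_terms(series, v_head_ml = v_head_ml)
  dco2_aq <- dissolved_pool_scale(soil) * terms$x_co2_slope
  co2_production <- terms$delta_co2 + dco2_aq
  o2_consumption <- -terms$delta_o2
  resp_o2 <- co2_production / soil$rq
  nit_o2 <- o2_consumption - resp_o2
  nit_n <- nit_o2 / soil$nitrification_o2_stoich
  respiration <- co2_production * M_CARBON / soil$soil_dry_weight_kg
  nitrification <- nit_n * M_NITROGEN / soil$soil_dry_weight_kg
  out <- tibble(
    respiration = respiration,
    gross_nitrification = nitrification,
    delta_n = terms$delta_n, delta_o2 = terms$delta_o2,
    delta_co2 = terms$delta_co2, delta_x = terms$delta_x,
    delta_co2_aq = dco2_aq,
    negative_rate_flag = respiration < 0 | nitrification < 0
  )
  class(out) <- c("rate_result", class(out))
  out
}

#' Apply a calibration set to raw sensor signals
#'
#' Converts a raw-signal incubation table (columns `signal_p_v`,
#' `signal_o2_v`, `signal_co2_v`) into calibrated measurands using one
#' calibration per sensor.
#'
#' @param raw Tibble with `timestamp_h`, `signal_p_v`, `signal_o2_v`,
#'   `signal_co2_v`, `t_head_k` (and optionally `t_soil_k`).
#' @param cals Named list of calibrations (`pressure`, `o2`, `co2`), each
#'   a [polynomial_calibration()] or fitted `baps_fit`.
#'
#' @return The calibrated series tibble (`p_hpa`, `o2_volpct`,
#'   `co2_umol_ml` added), preserving attributes such as `v_head_ml`.
#' @export
apply_calibrations <- function(raw, cals) {
  need <- c("timestamp_h", "signal_p_v", "signal_o2_v", "signal_co2_v", "t_head_k")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_data(paste0("raw series lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  stopifnot(all(c("pressure", "o2", "co2") %in% names(cals)))
  out <- dplyr::mutate(
    raw,
    p_hpa = evaluate_calibration(cals$pressure, .data$signal_p_v),
    o2_volpct = evaluate_calibration(cals$o2, .data$signal_o2_v),
    co2_umol_ml = evaluate_calibration(cals$co2, .data$signal_co2_v)
  )
  attr(out, "v_head_ml") <- attr(raw, "v_head_ml", exact = TRUE)
  out
}

#' Sensitivity of turnover rates to calibration perturbations
#'
#' Recomputes the respiration and gross nitrification rates of a raw
#' incubation under perturbed calibrations and reports the deviations
#' from the base rates, both absolute and relative. Typical perturbations
#' are the coefficient standard errors (`se_a`, `se_b`), the Monte Carlo
#' `me_y`-induced coefficient errors, and the systematic gas-error
#' (`gasE`) coefficient shifts.
#'
#' @param raw Raw-signal incubation tibble (see [apply_calibrations()]).
#' @param base_cals Named list of base calibrations (`pressure`, `o2`,
#'   `co2`).
#' @param perturbations Data frame with columns `label`, `sensor` (one of
#'   `"pressure"`, `"o2"`, `"co2"`), `da`, `db`: each row shifts that
#'   sensor's coefficients by `(da, db)`.
#' @param soil A [soil_params()] object.
#' @param v_head_ml Headspace volume (mL); defaults to the series
#'   attribute.
#'
#' @return A tibble with one row per perturbation: base and perturbed
#'   rates, absolute deviations `dev_respiration` / `dev_nitrification`
#'   and relative deviations in percent.
#' @export
perturbation_sensitivity <- function(raw, base_cals, perturbations,
                                     soil = soil_params(), v_head_ml = NULL) {
  if (!all(c("sensor", "da", "db") %in% names(perturbations))) {
    stop_data("perturbations need columns sensor, da, db (and optionally label).")
  }
  check_number(perturbations$da, "da")
  check_number(perturbations$db, "db")
  v_head_ml <- v_head_ml %||% attr(raw, "v_head_ml", exact = TRUE)
  base_series <- apply_calibrations(raw, base_cals)
  base <- turnover_rates(base_series, soil = soil, v_head_ml = v_head_ml)
  purrr::pmap_dfr(
    list(perturbations$sensor, perturbations$da, perturbations$db,
         perturbations$label %||% seq_len(nrow(perturbations))),
    function(sensor, da, db, label) {
      cals <- base_cals
      cal <- as_polynomial_calibration(cals[[sensor]])
      cals[[sensor]] <- polynomial_calibration(a = cal$a + da, b = cal$b + db,
                                               c = cal$c, d = cal$d, e = cal$e)
      pert <- turnover_rates(apply_calibrations(raw, cals), soil = soil,
                             v_head_ml = v_head_ml)
      tibble(
        label = as.character(label), sensor = sensor, da = da, db = db,
        respiration = pert$respiration,
        gross_nitrification = pert$gross_nitrification,
        dev_respiration = pert$respiration - base$respiration,
        dev_nitrification = pert$gross_nitrification - base$gross_nitrification,
        dev_respiration_pct = 100 * (pert$respiration - base$respiration) /
          base$respiration,
        dev_nitrification_pct = 100 * (pert$gross_nitrification - base$gross_nitrification) /
          base$gross_nitrification
      )
    }
  )
}

#' Summary over rates from multiple calibrations
#'
#' Mean, sample standard deviation (n-1) and coefficient of variation of
#' turnover rates recomputed under several calibrations — the standard
#' summary of how temporal calibration variability propagates into the
#' rates.
#'
#' @param rates A numeric vector of rates, or a data frame with columns
#'   `respiration` and/or `gross_nitrification` (e.g. stacked
#'   `rate_result` rows).
#'
#' @return A tibble with columns `quantity`, `mean`, `sd`, `cv_pct`, `n`.
#' @examples
#' multi_calibration_summary(c(408.3, 445.7, 413.7, 385.9, 402.4, 393.4))
#' @export
multi_calibration_summary <- function(rates) {
  summarise_vec <- function(x, name) {
    check_number(x, name)
    if (length(x) < 2) stop_data("need at least 2 rates to summarise.")
    tibble(quantity = name, mean = mean(x), sd = sd(x),
           cv_pct = 100 * sd(x) / mean(x), n = length(x))
  }
  if (is.numeric(rates)) return(summarise_vec(rates, "rate"))
  if (is.data.frame(rates)) {
    cols <- intersect(c("respiration", "gross_nitrification"), names(rates))
    if (!length(cols)) {
      stop_data("data frame input needs `respiration` and/or `gross_nitrification`.")
    }
    return(purrr::map_dfr(cols, function(cc) summarise_vec(rates[[cc]], cc)))
  }
  stop_data("`rates` must be numeric or a data frame.")
}
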