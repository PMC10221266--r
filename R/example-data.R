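## Bundled example records from a multi-year on-site calibration
## campaign on BaPS systems: one exemplary calibration per sensor
## (July 2015), its residual-variance budget, the 2012-2015 coefficient
## summary, and turnover rates of one incubation recomputed under six
## calibrations. Used throughout the documentation and the acceptance
## checks as realistic reference inputs.

#' Example calibration coefficients per sensor
#'
#' One exemplary on-site calibration (nine points, df = 7) per sensor,
#' with coefficient standard errors. Units: pressure in hPa (per V), O2
#' in Vol% (per V), CO2 in umol mL-1 (per V).
#'
#' @return A tibble with columns `sensor`, `a`, `b`, `se_a`, `se_b`,
#'   `df`.
#' @export
baps_example_coefficients <- function() {
  tibble(
    sensor = c("pressure", "o2", "co2"),
    a = c(699.6, -3.69, -0.015),
    b = c(250.1, 14.83, 0.52),
    se_a = c(1.14, 0.08, 0.0030),
    se_b = c(1.04, 0.05, 0.0020),
    df = 7L
  )
}

#' Example residual-variance budgets per sensor
#'
#' Residual variance `sigma2` of the exemplary calibrations and the
#' known measurement-error variance `me_y2`, in squared measurand units.
#'
#' @return A tibble with columns `sensor`, `sigma2`, `me_y2`.
#' @export
baps_example_variances <- function() {
  tibble(
    sensor = c("pressure", "o2", "co2"),
    sigma2 = c(0.154, 116e-6, 10e-6),
    me_y2 = c(0.003, 13e-6, 2e-6)
  )
}

#' Example multi-year coefficient summaries
#'
#' Means and standard deviations of the calibration coefficients over
#' six repeated calibrations (2012-2015).
#'
#' @return A tibble with columns `sensor`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `n`.
#' @export
baps_example_stability <- function() {
  tibble(
    sensor = c("pressure", "o2", "co2"),
    mean_a = c(699.3, -4.17, -0.02),
    sd_a = c(2.49, 0.76, 0.01),
    mean_b = c(250.6, 15.13, 0.54),
    sd_b = c(2.64, 0.39, 0.03),
    n = 6L
  )
}

#' Example turnover rates under six calibrations
#'
#' Respiration (ugC kg-1 sdw h-1) and gross nitrification
#' (ugN kg-1 sdw h-1) rates of one exemplary incubation, recomputed
#' under six calibrations performed between May 2012 and July 2015.
#'
#' @return A tibble with columns `calibration`, `respiration`,
#'   `gross_nitrification`.
#' @export
baps_example_rates <- function() {
  tibble(
    calibration = c("May 2012", "Nov 2012", "Aug 2014", "Nov 2014",
                    "Apr 2015", "July 2015"),
    respiration = c(408.3, 445.7, 413.7, 385.9, 402.4, 393.4),
    gross_nitrification = c(66.13, 59.42, 77.65, 84.48, 78.62, 77.67)
  )
}

#' Example reference gases for calibration validation
#'
#' Two certified reference mixtures used to cross-check fitted O2/CO2
#' calibrations (concentrations in Vol%, N2 remainder, 2% relative
#' accuracy each).
#'
#' @return A tibble with columns `label`, `frac_o2_volpct`,
#'   `frac_co2_volpct`, `rel_accuracy`.
#' @export
baps_reference_gases <- function() {
  tibble(
    label = c("A", "B"),
    frac_o2_volpct = c(17.6, 19.7),
    frac_co2_volpct = c(1.49, 0.50),
    rel_accuracy = 0.02
  )
}
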