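Package: bapscal
Title: Calibration and Uncertainty Toolkit for Barometric Process
    Separation (BaPS) Sensor Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality assurance for the sensor set (pressure, O2, CO2) of
    barometric process separation (BaPS) soil-incubation systems.
    Computes reference headspace gas compositions for stepwise on-site
    calibration via ideal-gas mole balances, fits and diagnoses linear
    calibration functions (ordinary least squares and the
    errors-in-variables functional model), propagates random and
    systematic measurement errors to concentrations, calibration
    coefficients and microbial turnover rates by Monte Carlo simulation,
    validates calibrations against reference gases, tracks sensor signal
    stability over repeated calibrations, and quantifies the sensitivity
    of respiration and gross nitrification rates to calibration shifts.
    Includes a synthetic-data generator emulating calibration runs,
    coefficient histories with controlled drift, and forward-simulated
    incubations with known turnover rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
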