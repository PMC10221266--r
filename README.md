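# bapscal

Calibration and uncertainty toolkit for the sensor set of barometric
process separation (BaPS) soil-incubation systems.

BaPS measures microbial respiration and gross nitrification in soil
cores simultaneously by balancing total and partial pressure changes in
a gastight isothermal chamber,

```
Δn = ΔO₂ + ΔCO₂ + ΔX ,
```

which makes the whole method only as good as the calibration of its
pressure, O₂ and CO₂ sensors (`y = a + b·x`, measurand per volt). Since
the manufacturer no longer recalibrates these instruments, users must
calibrate on site. This package is the computational side of that
workflow, for soil biogeochemists running BaPS (or similar closed-chamber)
systems:

* **reference values** — true headspace compositions through stepwise
  gas removal/injection cycles via ideal-gas mole balances
  (`baps_protocol()`, `run_protocol()`, `idealized_concentrations()`),
  headspace volume by Boyle's-law volume extension
  (`headspace_volume()`);
* **calibration fitting** — OLS with coefficient standard errors,
  confidence intervals `b ± t_crit·se_b`, Durbin–Watson and curvature
  diagnostics (`fit_ols()`), plus the errors-in-variables functional
  model (`fit_functional()`) that verifies sensor noise is small enough
  for ordinary regression;
* **error budgets** — sensor noise `me_x` and detection limits,
  measurand errors `me_y` analytically (pressure) and by Monte Carlo
  through the mole balance (O₂/CO₂), the residual-variance
  decomposition `t² = σ² − me_y²`, and the systematic calibration-gas
  error *gasE* with its closed-form geometric decay
  (`mc_concentration_errors()`, `decompose_variance()`,
  `propagate_gas_error()`);
* **validation & stability** — reference-gas slope cross-checks with a
  t-test (`slope_comparison_test()`), coefficient-series summaries and
  Mann–Kendall drift classification into *stable* / *signal-strength
  drift* / *response drift* (`stability_summary()`, `classify_drift()`);
* **rate sensitivity** — a documented simplified respiration /
  gross-nitrification separation model (`turnover_rates()`) used to
  quantify how calibration shifts move the rates
  (`perturbation_sensitivity()`, `multi_calibration_summary()`);
* **synthetic data** — seeded forward simulators for calibration runs,
  drifting coefficient histories and incubations with known rates
  (`simulate_calibration_run()`, `simulate_coefficient_history()`,
  `simulate_incubation()`).

Everything takes and returns tibbles, fitted objects have `tidy()` /
`glance()` / `autoplot()` methods, and a thin `baps` command-line
wrapper (subcommands `simulate | calibrate | uncertainty | validate |
stability | sensitivity`) is installed under `exec/`.

## Worked example

Simulate an on-site calibration run, fit the O₂ sensor, validate it
against two certified reference gases, and recover known turnover rates
from a simulated incubation:

```r
library(bapscal)

run <- simulate_calibration_run(seed = 42)
fit <- fit_ols(run$datasets$o2)
fit
#> <baps_ols> y = -3.816 + 14.91 x (k = 9 points)
#>   se_a = 0.0531, se_b = 0.0348, R2 = 0.99996, sigma2 = 4.819e-05, DW = 2.39
#>   95% CI(b): [14.83, 14.99]  (t_crit = 2.365, df = 7)
```

The slope 14.91 Vol% V⁻¹ carries a relative standard error of
0.23 % — the headline quality figure, since BaPS rates are computed
from measurand *changes*. Its 95 % interval is built from the
two-tailed t value at `df = k − 2 = 7`, and a Durbin–Watson statistic
near 2 indicates uncorrelated residuals.

```r
ref <- reference_slope(c(1.4356, 1.5772), c(17.6, 19.7)) # two reference gases
slope_comparison_test(fit, ref)
#>   difference        t   t_crit df significant within_ci_b
#> 1 0.07874282 2.265409 2.364624  7       FALSE        TRUE
```

The calibration slope is statistically indistinguishable from the
reference-gas slope (t < t_crit; the difference lies inside the slope's
confidence interval), so the calibration is validated.

```r
inc <- simulate_incubation(respiration = 400, nitrification = 75, seed = 42)
turnover_rates(inc)[, 1:2]
#> # A tibble: 1 × 2
#>   respiration gross_nitrification
#>         <dbl>               <dbl>
#> 1        400.                75.0
```

The rate model recovers the generative respiration
(µgC kg⁻¹ sdw h⁻¹) and gross nitrification (µgN kg⁻¹ sdw h⁻¹) from the
simulated sensor readings.

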