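---
title: "On-site BaPS sensor calibration: models, error budgets and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-site BaPS sensor calibration: models, error budgets and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapscal)
```

## The measurement problem

Barometric process separation (BaPS) measures microbial respiration and
gross nitrification in soil cores simultaneously, by balancing total and
partial pressure changes in a gastight isothermal chamber:

$$\Delta n = \Delta O_2 + \Delta CO_2 + \Delta X$$

where $\Delta n$ is the change in the total amount of headspace gas
(from pressure, temperature and headspace volume via the ideal gas law),
$\Delta O_2$ and $\Delta CO_2$ are the species changes measured by a
ZrO~2~ oxygen sensor and an infrared CO~2~ sensor, and $\Delta X$
collects all other gases. Because the method is a balancing approach,
everything rests on how accurately the three sensors translate raw
voltages into measurands. The instrument applies polynomial calibration
functions

$$y = a + bx + cx^2 + dx^3 + ex^4,$$

and in practice linear calibrations ($c = d = e = 0$) describe all
three sensors adequately over their measuring ranges. This package
implements the computational side of an on-site calibration and
quality-assurance workflow for such systems: reference-value
generation, calibration fitting and diagnostics, error budgets,
validation, stability tracking, and the propagation of calibration
errors into the turnover rates.

## Reference concentrations from mole balances

The O~2~ and CO~2~ sensors are calibrated simultaneously by repeated gas
exchange: the chamber is filled with synthetic air (20.5 % O~2~,
79.5 % N~2~), then a fixed gas volume is removed (pressure drop
$dP_{out}$) and replaced by a CO~2~/N~2~ mixture (pressure rise
$dP_{in}$). Amounts follow the ideal gas law with
$R = 8.314$ Pa m^3^ K^−1^ mol^−1^:

$$n = \frac{P\,V_{head}}{R\,T}, \qquad
  n_{i+1} = n_i - n_{out,i} + n_{in,i},$$

with removal taken proportionally to the current mole fractions
(well-mixed headspace — implied but not forced by the measurement
procedure; stated here as an explicit model assumption). Under
idealized conditions (constant $T$, $dP_{out} = dP_{in} = dP$) the
balance collapses to a geometric recursion, e.g.
$[O_2]_{i+1} = [O_2]_i\,(1 - dP/P)$; `idealized_concentrations()` is
that closed form and `run_protocol()` the stepwise engine, and the two
agree to 10 significant digits (a standing invariant of the test
suite). Internally everything is SI (Pa, m^3^, K, mol); hPa, mL, Vol%
and µmol mL^−1^ appear only at the I/O boundary, because mixing hPa
and Pa around the gas constant is the classic failure mode of these
computations. A convenient identity used throughout: a molar
concentration in mol m^−3^ is numerically the same value in
µmol mL^−1^.

The default protocol — 8 exchanges of $dP/P = 2\%$ at 1013.25 hPa,
293.15 K and 1000 mL — yields nine calibration points stepping O~2~
from 20.5 down to ≈ 17.5 Vol% and CO~2~ from 0 up to ≈ 3 Vol%, the
relevant measuring ranges of the two sensors. The headspace volume
itself is determined by isothermal volume extension; the exact
instrument formula is not public, so the package implements the
Boyle's-law form $V_{head} = (P_0 - dP)\,dV/dP$ with triplicates
averaged — a deliberate, documented choice.

## Calibration fitting and its diagnostics

`fit_ols()` collapses the ~10 replicate signal readings of each
calibration point to their mean and fits $y = a + bx$ by ordinary
least squares (`stats::lm`), reporting coefficient standard errors,
95 % confidence intervals $b \pm t_{crit}\,se_b$ (two-tailed Student
t, $df = k - 2$; $t_{crit} = 2.365$ at $df = 7$), $R^2$, the residual
variance $\sigma^2$, and the Durbin–Watson statistic of the
signal-ordered residuals. Because BaPS rates are computed from
measurand *changes*, the relative slope error $100\,se_b/|b|$ is the
headline quality figure; the intercept error is of minor importance.
Linearity is screened by a Wald test on an added quadratic term
(`residual_trend_test()`) — the data only say residuals "should show
no trend", so a specific, powerful test had to be chosen; the
quadratic Wald test plus the residual plot export is that choice.

### The errors-in-variables check

OLS assumes the signal (x) error is negligible. The functional model
drops that assumption:

$$y_i = a + b x_i + e_i,\quad e_i \sim N(0, \sigma^2); \qquad
  z_{ij} = x_i + g_{ij},\quad g_{ij} \sim N(0, \sigma_z^2),$$

with the true signals $x_i$ fixed unknowns observed $l$ times each. A
subtlety worth recording: the *joint* likelihood of this model is
unbounded — letting $\sigma^2 \to 0$ while the $x_i$ interpolate the
$y_i$ drives it to infinity — so naively maximising over all
parameters at once is ill-posed, and a quasi-Newton optimiser will
happily walk onto that ridge. `fit_functional()` therefore computes
the identified, consistent estimator for replicated designs:
$\sigma_z^2$ from the pooled within-point replicate variance, the
slope de-attenuated as $s_{xy}/(s_{xx} - \sigma_z^2/l)$, and
$\sigma^2$ as the residual variance minus the slope-leaked noise
component $b^2 \sigma_z^2 / l$. When replicates are identical the
corrections vanish and the fit *equals* OLS — which is exactly the
practical check the workflow needs: if functional and OLS coefficients
agree, sensor noise is small enough for ordinary regression. Parameter
recovery of all four parameters is verified by simulation in the test
suite (200 replicate fits, agreement within 3 Monte-Carlo standard
errors).

## The error budget

Three error classes are quantified separately, following the GUM
distinction between random and systematic components:

* **Sensor noise** $me_x$ (`estimate_sensor_noise()`): the sample
  standard deviation of the raw signal at constant conditions.
  Multiplied by the slope it bounds measurand precision
  (0.2 mV × 250.1 hPa V^−1^ ≈ 0.05 hPa for a typical pressure sensor),
  and three times that level is the conventional detection limit for a
  measured change.
* **Measurand error** $me_y$: for pressure, simply the manometer's
  0.2 % relative accuracy times the measured difference, averaged over
  the protocol (the span is small). For the gas concentrations, a
  Monte Carlo simulation (`mc_concentration_errors()`): every input of
  the mole balance ($V_{head}$, $P$, $T$, and per-step $dP_{out}$,
  $dP_{in}$, $T_{out}$, $T_{in}$) is drawn from a normal distribution
  and the protocol re-run, 1000 times by default; the across-run
  standard deviation of each step's concentration is its $me_y$. The
  input standard deviations are package defaults documented as
  assumptions (10 mL on $V_{head}$, 5 Pa on $P$, 0.2 % relative on
  each $dP$ plus the pressure-calibration slope error of 0.42 % added
  in quadrature — the "additionally considered" slope contribution is
  ambiguous in prose descriptions of such procedures, and quadrature
  is the conservative reading — and 0.1 K on temperatures). With these
  defaults the mean $me_y$ comes out near 0.003 Vol% O~2~ and
  0.0016 µmol mL^−1^ CO~2~: very small against the measured
  concentrations. Draws that are physically infeasible (negative
  pressure differences, exhausted pools) are rejected and counted,
  with a warning beyond 1 % rejections.
* **Systematic gas error** *gasE* (`propagate_gas_error()`): the
  2 % relative accuracy certified for the calibration gas cylinders is
  a *systematic* shift, not noise. Perturbing the two cylinders
  independently by ±2 % and re-running the balance gives the maximal
  deviation envelope: 0.41 Vol% on the initial O~2~ concentration,
  decaying geometrically as $0.41\,(1 - dP/P)^i$, and — because the
  balance is linear in the source compositions — coefficient shifts of
  exactly 2 % of $|a|$ and $|b|$ on refitting. This dwarfs the random
  $me_y$ by about two orders of magnitude and is the dominant
  calibration error source.

`decompose_variance()` closes the budget: $t^2 = \sigma^2 - me_y^2$
splits the residual variance into its known measurement-error share
and the irreducible "individual part" $t$; across the three sensors
$me_y^2$ explains only roughly 2–20 % of $\sigma^2$, i.e. calibration
accuracy is limited by the measuring system, not by the reference
procedure.

## Validation and stability

`reference_slope()` plus `slope_comparison_test()` implement the
reference-gas cross-check: two certified mixtures (17.6 % / 1.49 % and
19.7 % / 0.50 % O~2~/CO~2~) are measured and the two-point slope
compared with the calibration slope. A two-point line has no
conventional slope standard error, so the test is built on the
calibration fit's uncertainty, $t = |b - b_{ref}|/se_b$ with
$df = k - 2$ — equivalently, checking whether the reference slope
falls inside $CI_b$. This is a deliberate interpretation of an
under-specified "paired t-test on two slopes" and is stated in the
function documentation.

`stability_summary()` reduces a dated coefficient series to mean,
sample s.d. and CV (with $|mean|$ in the denominator, so negative
intercepts give positive CVs). `classify_drift()` formalises the
visual drift taxonomy — *stable*, *signal-strength drift* (trend in
$a$ only: offset aging), *response drift* (trend in $b$: changing
sensitivity, the serious failure mode) — with a Mann–Kendall monotone
trend test per coefficient (`stats::cor.test`, Kendall, exact for
short series). The two tests are Bonferroni-corrected at $\alpha/2$
each so the family-wise false-alarm probability on a stable sensor
stays at $\alpha$; with 8 calibrations and a 5 %/year drift the
classifier detects the drifting coefficient in > 95 % of simulated
histories while the false-positive rate stays below $\alpha$.

## The simplified rate model

The instrument's full rate algorithm is proprietary; this package
ships a deliberately simple, fully documented separation model used
*only* to quantify how calibration errors move the rates:

* total CO~2~ production = gaseous $\Delta CO_2$ + dissolved
  $\Delta CO_{2,aq}$, with the dissolved pool modelled as a linear
  Henry-type partition: capacity (0.33 mmol L^−1^ soil solution,
  interpreted as the dissolved amount per litre at a pure-CO~2~
  headspace) × solution volume × headspace CO~2~ mole fraction;
* respiratory O~2~ consumption = CO~2~ production / RQ (default 0.84);
* nitrification O~2~ = total O~2~ consumption − respiratory part,
  converted to N via 2 mol O~2~ per mol N
  (NH~4~^+^ + 2 O~2~ → NO~3~^−^), configurable;
* rates normalised by soil dry weight (12.011 g mol^−1^ C,
  14.007 g mol^−1^ N).

All molar change rates come from OLS slopes over the analysis window,
and $\Delta X$ closes the balance by construction. Negative computed
rates are flagged, never clipped. `simulate_incubation()` is the
matching forward model (explicit Euler at 0.005 h substeps), so
forward simulation followed by `turnover_rates()` recovers the
generative rates within 1 % noise-free — the round-trip consistency
check that pins both directions down. `perturbation_sensitivity()`
then re-derives the rates under shifted calibration coefficients; on
simulated incubations the gross nitrification rate is markedly more
sensitive than respiration (it is a difference of larger terms), and a
pressure *intercept* shift is nearly irrelevant because rates depend
on changes. Absolute sensitivities depend on the specific incubation
and are therefore reported per dataset, not asserted as constants.

## What the synthetic generator does and does not emulate

`simulate_calibration_run()`, `simulate_coefficient_history()` and
`simulate_incubation()` produce every input the analysis functions
consume: true linear (optionally mildly quadratic, since ZrO~2~
sensors are nominally non-linear) responses inverted to signals,
replicate noise at realistic levels (0.2 mV pressure, 0.15 mV O~2~,
7 mV CO~2~), measurand scatter matched to observed residual variances,
drifting coefficient histories, and incubations with known rates. One
explicitly seeded Mersenne-Twister stream per call makes every output
bit-reproducible. Not emulated: thermal transients, humidity (dry and
wet calibrations are equivalent in practice, and the workflow is
defined for dry conditions), carbonate-buffer kinetics, and sensor
failure modes beyond smooth drift — so green tests demonstrate
internal consistency and statistical calibration of the machinery, not
the behaviour of a physically aging sensor.

## Numerical choices and problem sizes

Tolerances follow the quantity's conditioning: mole-balance identities
are checked to 1e−10 relative, OLS/EIV equivalence to 1e−8, unit
round-trips to 1e−12. Monte Carlo sizes default to 1000 runs
(standard error of an s.d. estimate ≈ 2 % there); the test suite and
the acceptance script use 200–1000 replicates per stochastic check and
500 seeds for CI coverage, sizes chosen to keep each property's
Monte-Carlo error well inside its assertion band. Degenerate inputs
fail loudly with classed conditions: zero signal variance (singular
design), removal exceeding a gas pool (infeasible protocol),
$me_y^2 > \sigma^2$ (inconsistent budget), single replicates where
$\sigma_z^2$ is unidentified, and a signal spread smaller than the
signal noise (unidentifiable EIV slope).

## Known limitations

* The rate model is a simplification; agreement with the proprietary
  instrument software cannot be established from first principles, so
  rate *sensitivities* (relative deviations) are the meaningful
  output, not absolute rates.
* The MC input standard deviations are assumptions; conclusions that
  depend on the absolute size of $me_y$ (rather than its smallness
  relative to *gasE*) should re-run the budget with instrument-specific
  values.
* The gasE envelope treats the two cylinders as independent worst
  cases; correlated filling errors would need a joint specification.
* `pH`-dependent carbonate chemistry is out of scope; for soils above
  pH ≈ 6.5 the dissolved-CO~2~ term (and hence nitrification) is more
  sensitive to CO~2~ calibration than the linear partition suggests.
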