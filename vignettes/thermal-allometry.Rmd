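---
title: "Methods: allometric and thermal scaling of exploratory speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric and thermal scaling of exploratory speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoallo)
```

## The problem

Walking ectotherms such as carabid beetles explore their habitat at a routine
("exploratory") speed that depends on two traits above all: body mass and
body temperature. This package implements the full analysis chain for
quantifying that dependence from laboratory arena recordings:

1. raw x–y–t tracking trajectories → one exploratory-speed value per
   individual (`compute_speeds()`, `segment_bouts()`, `exploratory_speed()`);
2. multistart nonlinear least-squares fits of five thermal performance curve
   (TPC) families with AIC ranking (`fit_multistart()`, `compare_models()`);
3. a combined body-mass power law × modified Sharpe–Schoolfield model with
   estimation, prediction surfaces and residual extraction (`fit_allo_tpc()`,
   `predict_grid()`, `residual_table()`);
4. a sensitivity analysis testing group-wise residual means
   (`group_residual_test()`);
5. a synthetic-data generator emulating the study design
   (`generate_speed_dataset()`, `generate_trajectory()`, `generate_study()`),
   so every stage is testable without the original recordings.

## The combined model

Exploratory speed $v$ (m/s) as a function of body mass $M$ (mg) and
temperature $T$ (°C):

$$
v(M, T) \;=\; a_0\, M^{b}\;
\frac{\exp\!\left[\dfrac{-E}{k}\left(\dfrac{1}{T + 273.15} -
      \dfrac{1}{T_{\mathrm{ref}} + 273.15}\right)\right]}
     {1 + \dfrac{E}{E_h - E}
      \exp\!\left[\dfrac{E_h}{k}\left(\dfrac{1}{T_{\mathrm{opt}} + 273.15} -
      \dfrac{1}{T + 273.15}\right)\right]}
$$

with the Boltzmann constant $k = 8.617\times10^{-5}$ eV/K and reference
temperature $T_{\mathrm{ref}} = 15$ °C fixed (`tpc_constants`). The five free
parameters:

| parameter | units | meaning | start range |
|-----------|-------|---------|-------------|
| $a_0$ | m/s | speed of a 1 mg animal at $T_{\mathrm{ref}}$ | $[10^{-4}, 0.5]$ |
| $b$ | — | allometric exponent of the mass power law | $[-0.5, 1]$ |
| $E$ | eV | activation energy: steepness of the rise below the optimum | $[0.05, 2]$ |
| $E_h$ | eV | deactivation energy: steepness of the collapse above it | $E + [0.1, 10]$ |
| $T_{\mathrm{opt}}$ | °C | temperature of maximal speed | $[10, 40]$ |

Mass enters in mg, so $a_0$ reads "speed of a 1 mg animal at 15 °C". The
thermal term is the Sharpe–Schoolfield variant that carries $T_{\mathrm{opt}}$
as an explicit parameter; the curve's maximum falls *exactly* at
$T_{\mathrm{opt}}$ (setting the derivative of $\log v$ in $1/T$ to zero at
$T = T_{\mathrm{opt}}$ gives $-E/k + E/k = 0$), which the test suite verifies
against a dense-grid argmax oracle. Two closed forms the tests pin down:
doubling mass multiplies speed by $2^b$ at any temperature, and at
$T = T_{\mathrm{opt}}$ the thermal denominator collapses to $E_h/(E_h - E)$.

The objective is unweighted least squares on the natural speed scale (not log
speed): with multiplicative noise this slightly up-weights warm, heavy (fast)
individuals, but it is the convention for fitting such curves with `nls`-style
tools and keeps estimates comparable with that practice.

## From trajectory to exploratory speed

Image tracking records sub-millimetre "movement" even for inactive animals.
The filter therefore applies a hysteresis rule on per-frame speeds
(displacement / frame interval, mm/s): a movement bout opens when speed
reaches `v_start` = 0.6 mm/s and closes immediately before the first frame
below `v_stop` = 0.3 mm/s. Two thresholds prevent flicker at a single cutoff;
a bout still open at the end of the recording closes there. Exploratory speed
is then **total within-bout path length / total within-bout duration**
(converted to m/s) — a duration-weighted pooling, robust to how bouts happen
to be chopped up, rather than an arithmetic mean of per-frame speeds (the two
aggregations differ under within-bout speed variation; the pooled version is
the one consistent with "distance travelled while active"). An individual
that never opens a bout gets `NA`, never a zero, so inactivity cannot
masquerade as slowness in the fits. Thresholding acts on raw per-frame
speeds; an optional centred moving-average smoother exists (`smooth_window`)
but defaults off, and no minimum bout duration is imposed. Bout indices refer
to the speed series (entry $i$ = step from frame $i$ to $i+1$); the first
frame carries no speed.

## The TPC candidate set

`compare_models()` ranks five families (amplitudes bounded to (0, 1] m/s,
optima to [0, 60] °C):

* **gaussian** — $r_{\max} \exp(-\tfrac12 ((T - T_{\mathrm{opt}})/a)^2)$;
* **modified gaussian** — exponent 2 replaced by a free shape $b$ (reduces to
  the gaussian at $b = 2$, a test);
* **quadratic** — $a + bT + cT^2$, the only unbounded family, cross-checked
  against closed-form OLS;
* **weibull** — the 4-parameter Weibull TPC; below the support of its
  non-integer power the rate is defined as 0 rather than NaN so optimizer
  residuals stay finite;
* **pawar** — the thermal factor of the combined model with a single
  amplitude $r_{\mathrm{ref}}$ (rate at $T_{\mathrm{ref}}$); as
  $E_h \to \infty$ it converges to a pure Boltzmann–Arrhenius rise below the
  optimum (a limit test at $E_h = 50$ eV).

The registry pins one parameterisation per family; other variants of the
Weibull/modified-gaussian exist in the TPC literature, and AIC values are
comparable only within a fixed parameterisation.

AIC uses the Gaussian-likelihood convention of R's `AIC()` on `nls` objects,
$n\log 2\pi + n\log(\mathrm{RSS}/n) + n + 2(p+1)$, where the error variance
counts as a parameter. ΔAIC within a dataset is insensitive to the additive
constant and to the $+1$; absolute AIC is not, which matters when comparing
printed AIC tables across software. Ties in the ranking break by fewer
parameters, then name.

## Fitting machinery and numerical choices

`fit_multistart()` draws `n_starts` start vectors uniformly from the
per-parameter start ranges (a seeded stream, drawn start-by-start so the
first $k$ starts of a longer run coincide with a shorter run — which makes
"best RSS is non-increasing in `n_starts`" a testable property), runs bounded
Levenberg–Marquardt least squares from each (`minpack.lm::nls.lm`, `ftol` =
`ptol` = 1e-12, max 500 iterations), and keeps the converged solution with
minimum RSS. The winner is then polished with a few undamped Gauss–Newton
steps: L-M's stopping rule leaves the last couple of digits on the table
(near the optimum the deviance surface is flat at machine precision), and the
Gauss–Newton fixed point is the analytically accurate one — exact for the
quadratic family, where the fit matches `lm()` to ~1e-12.

The constraint $E_h > E$ is enforced by optimising
$\theta = \log(E_h - E)$ internally (gap bounded to $[10^{-4}, 30]$ eV);
estimates, standard errors and intervals are always reported on the natural
$E_h$ scale, with standard errors from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the public parameters ($J$ numerical,
$\hat\sigma^2 = \mathrm{RSS}/(n - p)$). Parameter combinations that evaluate
outside a model's support yield large finite residuals instead of NaN, so a
bad start fails gracefully rather than aborting the run. p-values are
two-sided Wald $t$ on $n - p$ degrees of freedom. Both Wald and
case-resampling bootstrap percentile intervals are offered; the bootstrap
(each replicate refit from the original estimates as its single start) is the
one to report for $E_h$, whose profile is strongly asymmetric — in noisy
replicates its interval can run into the upper gap bound, a visible symptom
of weak identification rather than a numerical failure.

`fit_allo_tpc()` defaults to `n_starts = 100` (against 250 for the pure TPC
fits): the 5-parameter problem converges to the same optimum from far fewer
starts given the informative start ranges, and the recovery experiments fit
100 such datasets. Identifiability guards reject single-mass (b) and
single-temperature (thermal parameters) designs outright.

## What the generator emulates — and what it does not

`generate_speed_dataset()` reproduces the study's design skeleton: 125
individuals, 8 species grouped into log-spaced mass classes spanning
10–303 mg (individual masses log-uniform within class), a 14-level
temperature gradient from 8–32 °C walked in blocks of 3 records per level,
and speeds drawn around the model expectation. Defaults that the study does
not pin down exactly and were chosen once:

* **Noise**: multiplicative lognormal, $\sigma_{\log} = 0.30$ — speeds are
  positive and their scatter grows with the mean; $\sigma_{\log} = 0.30$
  makes generated speeds span roughly the observed 0.008–0.11 m/s range
  under the default truth (a calibration choice). Note
  $E[v_{\mathrm{obs}}] = v_{\mathrm{pred}}\,e^{\sigma^2/2}$ (≈ +4.6%), so
  natural-scale least squares recovers $a_0$ with a small upward bias well
  inside the acceptance bands; an additive gaussian option exists for
  comparison. A per-species additive effect (`species_effect_sd`) defaults to
  0.
* **Exact temperature levels and species-to-class allocation**: even spacing
  and round-robin assignment (the study's exact tables are in unavailable
  supplements).

`generate_trajectory()` stands in for the camera pipeline with a two-state
(move/pause) correlated random walk in a 490 mm circular arena at 38 fps:
within bouts, per-frame speeds are lognormal around the target
(mean-calibrated, CV 0.2) and the heading performs a wrapped-normal walk
(sd 0.3 rad/frame); pauses jitter below 0.3 mm/s, emulating tracking noise of
inactive animals; the initial state is drawn from the two-state chain's
stationary distribution; the walk reflects off the wall (position mirrored
across the boundary and heading reflected about the tangent, so the walker
leaves the wall rather than grinding along it). It does **not** emulate
wall-following/thigmotaxis, temperature-dependent activity budgets, or
species-specific gaits — so round-trip tests demonstrate that the *filter and
fitting pipeline* is unbiased, not that real beetles behave like the walk.

Recordings in tests and the analysis scripts are 20–60 s rather than the
study's one hour: recording length only sets the precision of each
individual's speed estimate, and a few thousand frames already pin it to well
under 1%. `walk_config()`'s default duration stays 3600 s. The recovery
experiments use 100 replicates of $n = 125$ (the study size); the end-to-end
round trip uses 20 replicates.

All generators accept a seed and are pure functions of (configuration, seed),
restoring the global RNG state on exit.

## Sensitivity analysis

`group_residual_test()` fits `residual ~ 0 + group`, so each coefficient *is*
the group's mean residual, tested against zero with the pooled residual
variance (the linear-model convention; per-group Welch tests would differ for
very unbalanced groups). No multiplicity adjustment is applied, but a
Bonferroni column is reported alongside. With 8 species tested unadjusted at
$\alpha = 0.05$, some false positives per study are expected by construction
($0.95^8 \approx 0.66$ under independence; dependence through the shared fit
raises the no-hit probability, but not to 1), so a single flagged group in
one dataset is weak evidence of a real species effect — the Bonferroni column
is the sanity check. Groups with one observation are reported without SE/p.
A treatment-coded variant (`coding = "treatment"`) tests contrasts against a
baseline group instead.

## Known limitations

* The five TPC parameterisations are pinned to one variant each; AIC
  comparability across software depends on matching parameterisations and
  AIC conventions.
* $E_h$ is weakly identified with ~9 observations per temperature level and
  3–4 levels above the optimum; expect wide, asymmetric intervals.
* Natural-scale least squares under multiplicative noise is mildly
  heteroscedastic; a variance-stabilised (log-scale) fit is deliberately not
  offered to stay aligned with standard practice for these models.
* Predictions outside 8–32 °C or 10–303 mg extrapolate beyond the design the
  defaults emulate.
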