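# thermoallo

Allometric and thermal scaling of exploratory movement speed in walking
ectotherms (ground beetles), as a tested analysis pipeline.

Routine ("exploratory") movement speed drives encounter rates, interaction
strengths and habitat connectivity, and for ectotherms it depends above all
on body mass *M* and ambient temperature *T*. This package implements the
full chain for quantifying that dependence from laboratory arena recordings:
raw x–y–t tracking trajectories are filtered into one exploratory-speed value
per individual, five thermal performance curve (TPC) families are fitted and
ranked by AIC, and the selected Sharpe–Schoolfield-type curve is combined
with a body-mass power law into a single predictive model

```
v(M, T) = a0 · M^b · exp(−E/k · (1/(T+273.15) − 1/(Tref+273.15))) /
          (1 + E/(Eh−E) · exp(Eh/k · (1/(Topt+273.15) − 1/(T+273.15))))
```

with speed *v* in m/s, mass in mg, temperature in °C, the Boltzmann constant
k = 8.617·10⁻⁵ eV/K and Tref = 15 °C. `a0` is the speed of a 1 mg animal at
Tref, `b` the allometric exponent, `E` and `Eh` (eV) the activation and
deactivation energies governing the rise and collapse of speed around the
optimum temperature `Topt`, at which the curve peaks exactly. A sensitivity
analysis then asks whether model residuals deviate from zero for any species
or habitat-preference group. A synthetic-data generator (aggregated speed
tables and two-state correlated-random-walk arena trajectories) emulates the
study design — 125 individuals, 8 species spanning 10–303 mg, 14 temperature
levels from 8–32 °C — so every stage is testable without the original
recordings. The methods vignette (`vignettes/thermal-allometry.Rmd`) explains
the model, the filter, the fitting machinery and the generator in detail.

## Worked example

```r
library(thermoallo)

records <- generate_speed_dataset(seed = 1)   # 125 synthetic individuals
fit <- fit_allo_tpc(records, n_starts = 100, seed = 1)
print(fit)
```

```
Multistart NLS fit: allo_pawar (n = 125, 99/100 starts converged)
 parameter estimate std_error ci_lower ci_upper   p_value
        a0  0.03206  0.003884  0.02445  0.03967 2.271e-13
         b  0.12611  0.025994  0.07517  0.17706 3.716e-06
         E  0.41995  0.100615  0.22275  0.61715 5.700e-05
       E_h  2.21638  0.657011  0.92867  3.50410 1.000e-03
     t_opt 24.68689  0.936665 22.85106 26.52272 9.730e-52
RSS = 0.0353104, AIC = -654.7518
```

The generator's defaults draw speeds around the model surface at
(a0, b, E, Eh, Topt) = (0.03, 0.12, 0.37, 3.11, 26.33) with lognormal scatter
(σ_log = 0.30); this one dataset recovers them within roughly one standard
error each — e.g. a ~0.13 allometric exponent means a 10-fold heavier beetle
moves about 10^0.13 ≈ 1.35× faster at any temperature. Ranking the five TPC
families on the same speeds,

```r
compare_models(records$temperature, records$speed, n_starts = 100, seed = 1)
```

```
TPC model comparison (ranked by AIC)
             model n_params      aic delta_aic   ok
             pawar        4 -633.434  0.000000 TRUE
           weibull        4 -633.093  0.340658 TRUE
          gaussian        3 -631.906  1.527653 TRUE
 modified_gaussian        4 -631.007  2.426570 TRUE
         quadratic        3 -628.628  4.806331 TRUE
```

the generating (pawar) family wins, with the flexible Weibull close behind —
the same qualitative picture as fitting TPCs to field-style data, where
several unimodal shapes fit almost equally well.

## The analysis workflow

The `analysis/` scripts run the whole study on synthetic data and write
their tables under `results/`:

| script | does |
|--------|------|
| `01_simulate_study.R` | simulate 125 arena recordings + metadata |
| `02_exploratory_speeds.R` | trajectories → per-individual speed table |
| `03_fit_tpc_models.R` | five-family TPC comparison (AIC table) |
| `04_fit_allo_model.R` | fit the combined model; bootstrap CIs; residuals |
| `05_prediction_surfaces.R` | speed vs T at fixed masses and vs M at fixed temperatures |
| `06_residual_sensitivity.R` | group-wise residual tests (species, habitat) |

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

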