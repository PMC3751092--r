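# misurvsim

Simulation framework for studying how missing data in a **repeatedly
measured exposure** affect hazard-ratio estimation when the
**time-to-event outcome is fully observed** — the situation of a cohort
study that measures waist circumference at recruitment and again at a
follow-up wave, links colorectal-cancer incidence through registries, and
loses a sizeable fraction of the wave-2 measurements. The package is for
biostatisticians and epidemiologists who want a tested, reproducible
laboratory for comparing **complete-case analysis** with **multiple
imputation (MI)** under controlled missingness mechanisms.

## What it implements

The estimands are the log hazard ratios per 10 cm in two left-truncated
Cox models on the **age time scale** (entry at the wave-2 age):

- **model (a)** `log h_a(t) = log h_a0(t) + β_a1 (WC2−WC1)/10 + β_a2 WC1/10 + β_a3 Female + COB + Education`
- **model (b)** `log h_b(t) = log h_b0(t) + β_b1 WC2/10 + β_b2 Female + COB + Education`

Model (b) omits wave-1 waist, turning it into a *strong auxiliary
variable* (wave correlation 0.81) available only to the imputation model.

Around these sit:

- a synthetic cohort generator (age 40–69, sex, education, country of
  birth, smoking, physical activity, alcohol);
- a covariate-conditional bivariate-normal exposure model, calibrated in
  closed form so corr(WC1, WC2) = 0.81 with marginal mean 85 / SD 13 cm;
- Weibull proportional-hazards generation of cancer and death times,
  `S(t|lp) = exp(−scale · t^shape · e^lp)`, with administrative censoring
  6.1 years after wave 2 and the true HR per 10 cm set to 1.1 or 1.5;
- missingness mechanisms: MCAR (exact count) and two covariate-dependent
  MAR scenarios — a logistic model in WC1, age, sex and lifestyle
  covariates with intercept calibrated by bisection to hit 15/30/50%
  expected missingness, and an "enhanced" variant with doubled log odds
  ratios;
- a proper Bayesian normal-regression imputation engine with
  survival-aware predictors (cancer-vs-censored indicator and the
  left-truncation-aware Nelson–Aalen cumulative hazard), pooled by
  Rubin's rules `T = W + (1 + 1/m)B`;
- an experiment driver that crosses 2 HRs × 3 proportions × 3 mechanisms
  and reduces replicate estimates to bias, empirical SE and coverage with
  Monte Carlo errors, under per-replicate independent RNG streams.

See the vignette `vignettes/missing-exposure-simulation.Rmd` for the
modelling details and design decisions.

## Worked example

Simulate one cohort of 10,000, ampute half of the wave-2 measurements
under the enhanced covariate-dependent MAR scenario, and compare methods
for model (b):

```r
library(misurvsim)
cfg <- sim_config("desk", true_hr = 1.5, prop_missing = 0.5,
                  mechanism = "CDMAR_ENH", n = 10000)
d   <- sim_dataset(cfg, seed = 2026)
amp <- impose_cdmar(d, missingness_model("enhanced"), prop = 0.5, seed = 2027)

complete_case_estimate(amp, "b")
#> Cox model (b): log HR per 10 cm = 0.1601 (se 0.0295), 95% CI [0.1023, 0.2179]
#>   n = 5015, events = 1077

mi_estimate(amp, "b", m = 5, seed = 2028)
#> Pooled estimate 0.1824 (se 0.0292), m = 5, df = 15.1
#>   95% CI [0.1201, 0.2447]  W = 0.00042  B = 0.00037

fit_model_b(d)       # the complete-data fit the methods are chasing
#> Cox model (b): log HR per 10 cm = 0.2023 (se 0.0204), 95% CI [0.1622, 0.2424]
#>   n = 10000, events = 2219
```

The complete-case fit keeps the 5,015 subjects with an observed wave-2
measurement; MI uses all 10,000, with wave-1 waist informing the imputed
values, and lands closer to the complete-data estimate with a smaller
standard error than complete case. A full scenario cell aggregates this
comparison over replicates:

```r
cell <- run_cell(sim_config("desk", true_hr = 1.5, prop_missing = 0.5,
                            mechanism = "CDMAR_ENH", master_seed = 1))
cell$metrics[, c("analysis", "method", "bias", "emp_se", "coverage")]
#>   analysis        method         bias     emp_se coverage
#> 1        a complete_case  0.003367075 0.05719452   96.125
#> 2        a            MI -0.001109517 0.05976498   95.250
#> 3        b complete_case  0.002115634 0.04193233   96.000
#> 4        b            MI -0.001580630 0.03726394   95.500
```

Bias is a few thousandths of a log HR for either method, coverage sits at
the nominal 95%, and MI's empirical SE beats complete case for model (b)
— the auxiliary-variable precision gain.

`run_grid()` runs the full factorial and writes `metrics.csv`,
`reference.csv` and bias/SE/coverage figures;
`inst/scripts/misurvsim-cli.R` wraps the same entry points for shell use.

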