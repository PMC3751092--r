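---
title: "Simulating missing data in a repeated exposure with a survival outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating missing data in a repeated exposure with a survival outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(misurvsim)
```

## The question the simulation answers

Cohort studies with repeated follow-up waves routinely lose a substantial
fraction of participants at the later waves, so a repeatedly measured
exposure -- here waist circumference, measured at recruitment (wave 1) and
again 13 years later (wave 2) -- is often missing at wave 2 even when the
outcome, incident colorectal cancer, is completely ascertained through
registry linkage. The analyst must then choose between deleting the
incomplete records (complete-case analysis) and multiply imputing the
missing measurements. `misurvsim` implements a full simulation laboratory
for that comparison: it generates cohorts in which the truth is known,
imposes missingness by controlled mechanisms, applies both methods, and
scores them by bias, empirical standard error and interval coverage.

Two epidemiological analyses are studied, both Cox proportional-hazards
models with **age as the time metric** and delayed entry at the wave-2 age:

* **Model (a)** -- the exposure of interest is the *change* in waist
  circumference, \((WC_2 - WC_1)/10\) (per 10 cm), adjusted for wave-1
  waist \(WC_1/10\), sex, country of birth and education.
* **Model (b)** -- the exposure of interest is wave-2 waist \(WC_2/10\),
  with the same adjustment set *minus* wave-1 waist. Because the two waves
  correlate at 0.81, wave-1 waist then becomes a *strong auxiliary
  variable*: absent from the analysis model yet available to the
  imputation model, which is the configuration under which multiple
  imputation can recover real precision.

## The generating model

### Covariates

Baseline covariates are synthetic: age uniform on [40, 69] years, a female
indicator (prevalence 0.59, matching the reported cohort composition of
24,469 women among 41,514 recruits), and five categorical factors
(education, country of birth, smoking, physical activity, alcohol) with
round plausible prevalences (`default_prevalence()`). The source cohort's
covariate rows are not deposited, so marginals are design choices; what
the study's conclusions rest on is the *dependence of the downstream
models on the covariates*, which is fully specified below. Covariates are
mutually independent by default; a `smoking_by_sex` hook in
`cohort_config()` lets smoking prevalences differ by sex when covariate
dependence is wanted.

### Exposures

Given covariates \(X\), the two waist measurements are one bivariate
normal draw per subject,
\[
  (WC_1, WC_2) \mid X \sim N_2\!\big(
   (\beta_0 + b'X,\; \beta_0 + \Delta + b'X),\; \Sigma \big),
\]
with shared slopes \(b\) (`default_exposure_coef()`), a mean wave-2 gain
\(\Delta = 1.5\) cm, and residual covariance \(\Sigma\) calibrated in
closed form: writing \(v = \operatorname{Var}(b'X)\) (computed exactly by
enumerating the categorical joint distribution plus the uniform age term),
the residual variance is \(s^2 = 13^2 - v\) and the residual correlation
\(r = (0.81 \cdot 13^2 - v)/s^2\). This makes the marginal scale mean 85
cm / SD 13 cm and the marginal wave-1/wave-2 correlation exactly 0.81 --
the one reported constraint on the exposure model -- while the slopes give
the covariate/waist correlations their observed signs and rough sizes
(for example, female \(-13.7\) cm yields a correlation near \(-0.52\)).
Only the 10-cm unit matters for the estimands, so the marginal scale is a
convention, overridable in `exposure_params()`.

### Outcomes

Time to colorectal cancer and time to death (a censoring cause) are
independent given covariates, each Weibull proportional hazards on the
years-from-wave-2 clock, \(S(t \mid \mathrm{lp}) = \exp(-\lambda t^{k}
e^{\mathrm{lp}})\), sampled by inverse transform (`weibull_time()`). The
cancer linear predictor contains the change in waist (coefficient
\(\log(\mathrm{HR})/10\) per cm, with HR 1.1 or 1.5 the configured truth),
wave-1 waist, sex, age, education and country of birth; the death
predictor sex and age. Follow-up is censored administratively 6.1 years
after wave 2 (the span from the median wave-2 attendance date to the end
of registry follow-up). Records are then re-expressed on the age clock,
`entry_age = age + wave_gap`, so the analysis models are left-truncated.

The shape/scale and nuisance coefficients were never published; the
defaults are package choices targeting roughly 2.5% cancer incidence and
10% mortality over the window at full scale. They affect precision, not
the estimand: the one structural constraint, verified by test, is that a
correctly specified complete-data fit recovers \(\log(\mathrm{HR})\).

### Missingness

Only wave-2 waist is ever amputed (wave 1 was ~99% complete in the source
cohort). Three mechanisms are implemented at targets 15/30/50%:

* **MCAR** removes an exact-count simple random subset.
* **Standard covariate-dependent MAR**: a logistic model in wave-1 waist
  (odds ratio 1.10 per 10 cm), age (1.06 per year), sex and the
  categorical covariates, using the odds ratios observed for wave-2
  non-attendance (`mar_scenario_table()`).
* **Enhanced covariate-dependent MAR** doubles every log odds ratio
  (squares the odds ratios) for a more extreme but still realistic
  scenario.

The logistic intercept is calibrated by bisection (`calibrate_intercept()`,
tolerance \(10^{-6}\) on the *expected* proportion, deterministic given
the table); missingness indicators are then independent Bernoulli draws,
so realised proportions are stochastic around the target -- whereas MCAR
uses an exact count, mirroring the different phrasings "selected a random
sample" versus "determined (by iteration) ... approximately". The
mechanism never reads `wc2` itself, so it is genuinely
covariate-dependent MAR, not MNAR; outcome-dependent missingness is out
of scope.

## The two methods

**Complete-case analysis** deletes rows with missing `wc2` and fits the
Cox models with Breslow tie handling (ties have probability ~0 with
continuous ages, but the rule is fixed for reproducibility); the fitting
core delegates to `survival::coxph()` with `Surv(entry, exit, event)`
left truncation, and single fits report Wald 95% intervals.

**Multiple imputation** (`impute()`) draws missing `wc2` from a proper
Bayesian normal linear regression: with noninformative prior on
\((\beta, \log\sigma)\), it draws \(\sigma^{*2} = \mathrm{RSS}/\chi^2_{n-k}\),
then \(\beta^* \sim N(\hat\beta, \sigma^{*2}(X'X)^{-1})\), then adds
residual noise -- both parameter and residual uncertainty propagate into
the between-imputation variance. The imputation model contains the
analysis covariates, the lifestyle auxiliaries (smoking, physical
activity, alcohol), a cancer-versus-censored event indicator, and the
Nelson--Aalen cumulative hazard at the subject's exit age computed with
left-truncation-aware risk sets (`nelson_aalen()`), entered untransformed
-- the survival-aware design recommended in the imputation literature in
preference to log time plus status. Two deliberate modelling choices
follow the applied setting: the *wave-2 measurement* is imputed and the
change recomputed afterwards (an analyst facing a variable complete at
wave 1 and missing at wave 2 would do exactly that, at the price of only
semi-compatibility with analysis (a)); and the hazard enters on the age
clock, consistent with the analysis time scale (the alternative
study-time clock is defensible; the choice is noted as an
interpretation). Per-imputation estimates are pooled by Rubin's rules
(`rubin_pool()`): \(\bar q\), \(W\), \(B\), \(T = W + (1 + 1/m)B\),
small-sample degrees of freedom \((m-1)(1 + W/((1+1/m)B))^2\) and a
t-based interval; \(B = 0\) degenerates to the normal interval.

## The experiment and its metrics

A scenario cell (`run_cell()`) repeats generate → ampute → analyse for
`nsim` replicates and reduces each (analysis, method) series to

* **bias** -- mean estimate minus truth, in log-HR units;
* **empirical SE** -- SD of the estimates across replicates;
* **coverage** -- percentage of 95% intervals containing the truth;

with Monte Carlo errors \(\mathrm{emp\_se}/\sqrt{\mathrm{nsim}}\) and
\(\sqrt{c(1-c)/\mathrm{nsim}}\). Truth for model (a) is
\(\log(\mathrm{HR})\) by construction. Model (b) fits a model different
from the generator (no wave-1 adjustment), so its reference value is the
mean complete-data model-(b) estimate over `nsim_ref` un-amputed
replicates, and each analysis's "complete" SE is the mean complete-data
model SE (`complete_reference()`). `run_grid()` crosses 2 hazard ratios
× 3 proportions × 3 mechanisms (18 cells, 72 metric rows) and can write
the metrics table, the reference table and bias/SE/coverage figures.

### Seeds and failure policy

All replicate randomness derives from one master seed via independent
L'Ecuyer-CMRG streams (`rng_streams()`); imputations use sub-streams of
the replicate stream. Any replicate can therefore be re-run in isolation
(`run_replicate(cfg, index = i)`) and reproduce its estimates exactly --
a modernisation of fixed-stride seed separation, which is
generator-specific and fragile. A replicate that errors is logged; a cell
aborts when more than 1% of replicates fail, because silently dropping
failed replicates would bias the metrics.

## Profiles and problem sizes

The **full** profile encodes the study conditions: cohorts of 41,476,
1,000 replicates per cell, m = 20 imputations, 10,000 reference
replicates (at those sizes the log HR is estimated to within about 1.5%
of truth; expect hours per grid on one CPU). The **desk** profile is the
package's scaled-down evaluation setting: n = 5,000, 800 replicates,
m = 5, 500 reference replicates, and an event-rich cancer model (constant
hazard, scale inflated to ~20% incidence, age coefficient reduced to
0.01). Three properties motivate it: the replicate count is chosen so
Monte Carlo error on bias, emp SE/√nsim with emp SE ≈ 0.06 at this size,
sits near 0.002 log-HR units — small enough to resolve biases of order
0.005 (at 200 replicates the allowance would exceed the bias bounds being
checked, making the check uninformative); a higher event fraction
shrinks the per-replicate SE; and with shape 1 the cancer hazard is
constant in time, so a static age effect folds into the age-scale
baseline hazard and the analysis model remains essentially correctly
specified even at a 20% event fraction -- replicated complete-data runs
put its intrinsic bias within 0.004 of zero. (At full scale, with ~2.5%
incidence, the shape-1.5 model's attenuation is negligible; at 20% events
it would not be, which is why the desk profile changes shape rather than
only scale.) The test suite checks distributional and recovery
properties at sizes between 2,500 and 100,000 chosen so each check's
Monte Carlo tolerance is sharp enough to be informative.

```{r, eval = FALSE}
cfg <- sim_config("desk", true_hr = 1.5, prop_missing = 0.5,
                  mechanism = "CDMAR_ENH", master_seed = 1)
cell <- run_cell(cfg)
cell$metrics[, c("analysis", "method", "bias", "emp_se", "coverage")]
```

## What the generator does and does not emulate

The synthetic cohort reproduces the *structure* that drives the
missing-data comparison: the covariate-conditional correlation of the two
exposure waves, proportional-hazards outcomes with a known exposure
effect, left truncation on the age scale, and missingness odds tied to
observed covariates. It does not reproduce the source cohort's covariate
joint distribution (beyond the optional sex-smoking hook), its
recruitment and attendance dates (all subjects share `wave_gap = 13`
years and one administrative window), non-normal exposure distributions,
measurement error, or mortality before wave 2. Passing tests therefore
support conclusions about the *methods* under these mechanisms, not
about any particular cohort's parameter values; and because the published
record fixes only the exposure effect, the wave correlation and the
missingness odds ratios, quantities that depend on unpublished nuisance
parameters (for instance the model-(b) reference hazard ratio) are
reported relative to this package's own reference run, not as
reproductions of externally reported values.

## Numerical choices and degenerate inputs

* Bisection for the missingness intercept brackets \([-50, 50]\) and
  fails loudly outside it (pathological coefficients).
* A zero residual covariance is accepted and returns the conditional
  means exactly (useful for deterministic checks); any other non-positive
  -definite matrix is rejected.
* An imputation design with collinear columns raises an error naming the
  offending columns; an exact linear fit (RSS = 0) degenerates to
  deterministic imputation.
* `rubin_pool()` requires at least two imputations (the between variance
  is otherwise undefined) and treats \(B = 0\) as the large-df limit.
* Cox fits refuse data with missing analysis variables, fewer than two
  events, or a zero-variance exposure, rather than returning fragile
  estimates.

## Known limitations

Missingness mechanisms depending on the outcome or on the missing values
themselves (MNAR) are not implemented; only two waves are supported; the
imputation engine is single-variable by design (only `wc2` is ever
missing), not chained equations. Full-scale grid runs are
computationally serious (order of an hour per cell on one CPU) and are
configured, but the shipped checks run the desk profile.
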