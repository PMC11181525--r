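---
title: "Missing-data strategies for a survey-weighted Weibull AFT risk model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data strategies for a survey-weighted Weibull AFT risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Population risk-prediction models built from pooled health-survey cycles
face item non-response in their predictors. How the missing cells are
handled — dropping incomplete records, filling with stratum modes, or
drawing from conditional models once or repeatedly — changes both the
fitted model and the headline performance measures. `aftmiss` packages
the whole comparison: a synthetic survey cohort with a *known* outcome
process, the four classical strategies, a survey-weighted Weibull
accelerated failure time (AFT) model of five-year premature mortality
(death before age 75), and six validation measures.

Because the real linked survey/vital-statistics microdata this design
mirrors are access-restricted, the package's synthetic generator is a
first-class module: every downstream claim is tested against ground
truth that the generator exposes.

## The outcome model

Survival time follows a log-linear location–scale model,

$$\log T = \mu + x^\top\beta + \sigma W, \qquad
  W \sim \text{standard minimum extreme value},$$

so $S(t\mid x)=\exp\!\big(-\exp\!\big(\tfrac{\log t-\mu-x^\top\beta}
{\sigma}\big)\big)$, a Weibull AFT with scale $\sigma$ (shape
$1/\sigma$). The hazard ratio of a covariate level is
$\mathrm{HR}=\exp(-\beta/\sigma)$. Fitting maximizes the weighted
log-likelihood (censored rows contribute $\log S$, events the log
density), with the covariance of $(\mu,\beta,\log\sigma)$ taken from the
inverse observed information (`survival::survreg` is the optimizer
behind `fit_weibull_aft()`). Sex-specific models are fitted and reported
independently.

Survey weights are pooled across cycles, divided by the number of
cycles, and rescaled to mean one before likelihood work; weighted point
estimates are invariant to that rescaling and every performance measure
is invariant to global weight rescaling (a property the test suite
checks). A robust sandwich variance is not provided; the model-based
covariance is used throughout.

## What the generator emulates — and what it does not

`generator_config()` fixes the cohort's stated world:

* six survey cycles; cycle uniform per subject; weights log-normal
  (log-sd 0.5) divided by the cycle count;
* age drawn from six band marginals (18–24 … 65–74), uniform within a
  band, so the "75th birthday" censoring bound is well defined;
* categorical predictors drawn jointly through a Gaussian copula with a
  single exchangeable latent correlation (default 0.2), cut at the
  marginal quantiles. The marginals follow the published baseline
  distribution of the pooled survey cohort; the copula correlation is a
  stand-in for an unknown dependence structure, not an estimate;
* true coefficients derived from published mode-imputation hazard
  ratios via $\beta=-\sigma\log(\mathrm{HR})$ with $\sigma=0.82$ (the
  fitted-scale neighbourhood of the published models), age at HR
  1.08/year; all overridable;
* the intercept $\mu$ is calibrated so the expected event fraction hits
  the target five-year premature-death rate (1.41% female, 2.06% male).
  On the fixed probe sample the condition "death by
  $\min(\text{horizon},75-\text{age})$" is linear in $\mu$, so the
  root-finding problem is solved exactly by quantile inversion of the
  per-subject thresholds;
* administrative censoring at 5 years or the 75th birthday; optional
  independent exponential censoring (off by default) exists solely to
  exercise the inverse-probability-of-censoring (IPCW) code paths.

Missingness defaults mirror the published per-variable rates (income
≈10.9%/8.2%, education 4.5%/6.0%, BMI, smoking 1.5–3.5%, chronic
conditions ≈0.1%). Variables above 1% are missing at random (MAR) with
log-odds +1 on the death indicator — chosen once as "decedents are
about $e$ times as likely to skip an item" — the rest are missing
completely at random (MCAR). The MAR intercept is solved by
root-finding on the cohort itself to hit the marginal rate within 1e-3.

Limits worth keeping in mind: the generator does not reproduce the
survey's complex design (clusters, strata, replicate weights), item
non-response *co-occurrence* beyond what the shared death-indicator
driver induces, or MNAR mechanisms. One visible consequence: with
near-independent per-variable puncturing, complete-case removal lands
around 20% rather than the published 16–17%, because real
non-response clusters within questionnaire sections. A green test
therefore establishes that the *machinery* behaves as specified under a
stated world, not that the synthetic cohort is a statistical twin of
the restricted data.

## The four strategies

* **Complete case** — drop any row with a missing model predictor.
* **Mode** — fill each cell with the unweighted modal category of its
  variable within the sex-stratified cycle; ties break to the first
  roster level, deterministically.
* **FCS single imputation** — fully conditional specification within
  each stratum: initialize with stratum modes, then five burn-in sweeps
  over the incomplete variables in order of increasing missingness,
  refitting each variable's conditional model on its originally
  observed rows (all other roster variables, age, and the outcome as
  covariates) and redrawing the missing cells.
* **FCS multiple imputation** — the same chain run five times with
  seeds `seed + d`, giving five completed datasets; estimates are
  pooled by Rubin's rules ($\bar q$, within-variance $W$,
  between-variance $B$, total $T=W+(1+\tfrac1m)B$, the classic
  small-sample degrees of freedom).

Design choices where the design was genuinely open:

* **Outcome representation.** The outcome enters every conditional
  model as *two* covariates — the event indicator and log follow-up
  time — standard survival-imputation practice; switchable off. The
  property suite shows what the switch buys: under MAR-on-outcome
  missingness, imputing *without* the outcome attenuates the imputed
  covariate's fitted coefficient toward zero, while the scale parameter
  is essentially insensitive to the choice.
* **Conditional engines.** Binary variables use ridge-penalized
  logistic regression; nominal variables use ridge-penalized
  multinomial logistic regression (filling the modelling role that a
  discriminant function plays in some software); ordinal variables use
  proportional-odds logistic regression. The ordinal and multinomial
  Newton solvers are implemented in-package (with `MASS::polr` and a
  direct likelihood maximization serving as independent oracles in the
  tests); the fixed weakly-informative ridge ($\tfrac12\lambda n
  \|\theta\|^2$, $\lambda=10^{-4}$, cutpoints unpenalized) resolves
  perfect separation and empty dummy columns. Failure falls back to
  multinomial, then to a stratum-marginal draw, with the engine used
  recorded per variable.
* **Proper imputation.** Before each draw the conditional-model
  parameters are perturbed by a draw from the normal approximation to
  their posterior; single imputation is simply the $m=1$ special case.
* **Weights.** Survey weights are *not* used inside conditional
  imputation models (the posterior draw stays well-defined); a flag
  turns weighting on.
* **Low-prevalence conditions.** Binary chronic-condition indicators
  with under 1% missingness are deterministically filled with the
  absent level before FCS — a convergence safeguard for rare
  conditions.
* **Strata fallbacks.** A variable with no observed values in a stratum
  (the "question not asked in cycle 1" situation) is imputed from
  configured replacement strata (`fallback_strata`), generalizing the
  hard-coded variable-specific rule.
* **Leakage.** Conditional models only ever see rows of their own
  stratum (or the configured fallback strata); an instrumentation flag
  records the strata used by every fit so the tests can audit this.

## Performance measures

All six are computed at the five-year horizon (the design ties every
prediction to five years; per-measure horizons are not separately
specified, so one horizon is used consistently):

* **Nagelkerke $R^2$** from the fitted and null weighted log-likelihoods
  with $n$ = effective sample size (sum of mean-one weights).
* **Integrated Brier score**: Graf-style IPCW decomposition, censoring
  survival $\hat G$ by weighted Kaplan–Meier with events/censorings
  swapped, left limits at event times, trapezoidal integration over the
  event-time grid augmented with $\{0,\tau\}$, divided by $\tau$;
  contributions with $\hat G=0$ are dropped and counted.
* **Harrell's c-index**: comparable pairs $(i,j)$ with $t_i<t_j$,
  $\delta_i=1$; risk ties count ½; *unweighted* pairs by default (the
  weighted-pair variant is a switch).
* **Discrimination slope**: difference in weighted mean predicted risk
  between subjects dead by year 5 and subjects with event-free
  follow-up of at least 5 years. Subjects administratively censored at
  the 75th birthday before year 5 are excluded by default (a flag
  reclassifies them as non-events).
* **Calibration-in-the-large**: (1 − KM survival at 5y) minus weighted
  mean predicted risk; negative means overprediction.
* **Calibration slope**: coefficient on the frozen linear predictor
  when a Weibull AFT with own intercept and scale is refitted to the
  same data. On development data this is exactly 1 (the original MLE
  makes the restricted score vanish at slope 1), which is what the
  published models report and what the acceptance target checks to
  four decimals.

For multiple imputation the six measures are reported per dataset with
their (min, max) range; hazard ratios, by contrast, are Rubin-pooled —
mirroring the reporting convention of the study design (ranges for
performance, pooled intervals for effects).

## Numerical choices

* Newton solvers: gradient tolerance `1e-7` (`1e-5` inside imputation
  chains, where posterior-draw noise dominates), step damping at norm
  10, cutpoint ordering preserved by step halving, warm starts across
  FCS sweeps.
* `survreg` runs with `maxiter = 100`, `rel.tolerance = 1e-10`. Two
  stabilizations wrap it. First, the weighted fit occasionally
  collapses (scale toward 0 or infinity) from its default
  initialization when ~98% of the mass sits at the horizon; the fitter
  then re-initializes from the stable unweighted fit and, if needed,
  retries up to three jittered restarts. Second, a factor level with
  subjects but zero events makes the MLE diverge (the likelihood
  optimum sits at coefficient $+\infty$); such levels get one
  pseudo-event row at weight $10^{-3}$ before fitting, which yields a
  large-but-finite coefficient with an enormous standard error, moves
  every other estimate by $O(10^{-3})$, and keeps encodings and
  covariance dimensions intact for pooling. Stabilized levels are
  recorded in `fit$stabilized_levels`. Remaining inestimable
  coefficients raise an error naming the term.
* Intercept calibration and MAR-rate calibration must land within 1e-3
  of their targets or they error.
* Every random stage (probe sample, cohort draw, puncturing, each FCS
  chain) derives its own 32-bit seed from the user seed, so all outputs
  are bit-for-bit reproducible.

## Scale choices in the tests

The acceptance criteria run at desk scale (n = 20,000 per cohort, 20
seeds) rather than the published cohort sizes (~250,000): at 20,000
subjects and a 1.4% event rate, rare levels (e.g. stroke, 0.8%
prevalence) occasionally have no events, which inflates one dummy's
standard error without disturbing the scale parameter or the
income-quintile contrasts the criteria examine. The external-validation
calibration-slope check uses an event-rich configuration (20% events,
n = 100,000) because at the published event rate the Monte Carlo spread
of the slope exceeds the ±0.03 band the property asserts.

## Known limitations

* Complete-case removal percentages undershoot the published ones (see
  above); directions, not magnitudes, are the tested claims.
* The c-index definition excludes tied-time pairs entirely
  ($t_i<t_j$ strictly), which can differ in the fourth decimal from
  implementations that count event–censored ties as comparable.
* No predictive-mean matching, joint-model imputation, MNAR sensitivity
  analyses, bootstrap replicate-weight variance, or Cox baselines.
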