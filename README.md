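# aftmiss

Compare four missing-data strategies — complete case, stratified mode
imputation, fully conditional specification (FCS) single imputation and
FCS multiple imputation — on a **survey-weighted Weibull accelerated
failure time (AFT) model** of five-year premature mortality (death
before age 75), the way population risk-prediction models are built
from pooled national health-survey cycles.

The package is aimed at biostatisticians and epidemiologists who want
to study, on fully reproducible synthetic cohorts with a *known*
outcome process, how the choice of imputation method moves model
parameters, hazard ratios and predictive-performance measures.

## The model

Log survival time follows a location–scale model with minimum
extreme-value errors,

```
log T = mu + x'beta + sigma * W,     S(t|x) = exp(-exp((log t - mu - x'beta)/sigma))
```

i.e. a Weibull AFT with scale `sigma` and shape `1/sigma`; the hazard
ratio of a covariate level is `exp(-beta/sigma)`. Fits are
survey-weighted (pooled weights divided by the number of cycles,
rescaled to mean one), sex-specific, and validated with six measures:
Nagelkerke R², IPCW integrated Brier score (Graf), Harrell's c-index,
time-specific discrimination slope, calibration-in-the-large, and
calibration slope, plus decile calibration curves.

Multiply-imputed estimates are pooled with Rubin's rules
(`T = W + (1 + 1/m) B`); MI performance measures are reported as
per-dataset (min, max) ranges.

## Worked example

```r
library(aftmiss)

cfg    <- generator_config("female", n = 20000, seed = 1)   # 1.41% 5-year deaths
cohort <- generate_cohort(cfg)                              # complete cohort
punct  <- apply_missingness(cohort,
            default_missingness("female", seed = 1))$cohort # MAR-on-outcome

report <- run_comparison(punct, seed = 1)                   # all four methods
print(report)
```

```
<comparison_report> sex=female, n=20000
  complete_case scale=0.7366-0.7366  c-index=0.8176-0.8176
  mode          scale=0.7579-0.7579  c-index=0.8195-0.8195
  fcs_single    scale=0.7585-0.7585  c-index=0.8181-0.8181
  fcs_multiple  scale=0.7580-0.7591  c-index=0.8159-0.8186
```

Read-out: the three imputation-based methods agree closely with each
other on the Weibull scale (0.7579–0.7591) while complete case sits
visibly apart (0.7366) — the MAR-on-outcome mechanism removes decedents
preferentially, biasing the scale, exactly the complete-case failure
mode the comparison is designed to expose. MI rows show (min–max)
across the five imputed datasets.

Individual stages are available as plain functions:
`impute_cohort()`, `fit_weibull_aft()`, `hazard_ratios()`,
`pool_rubin()`, `performance_report()`, `calibration_curve()`,
`baseline_table()`, `stratified_calibration()`.

On development data the calibration slope is exactly 1:

```r
fit <- fit_weibull_aft(cohort)
calibration_slope(fit, cohort)
#> [1] 1
```

## Command line

```sh
Rscript inst/cli/aftmiss.R generate --sex female --n 20000 --seed 1 \
    --out cohort.csv --mask-out mask.csv --params-out params.json
Rscript inst/cli/aftmiss.R impute --method multi --m 5 --burnin 5 \
    --strata sex,cycle --seed 1 --in cohort.csv --out-dir imp/
Rscript inst/cli/aftmiss.R fit --in imp/imputed_1.csv --out fit.json
Rscript inst/cli/aftmiss.R evaluate --fit fit.json --in imp/imputed_1.csv \
    --horizon 5 --out report.json --calibration-out calib.csv
Rscript inst/cli/aftmiss.R compare --sex female --n 20000 --seed 1 --out-dir results/
```

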