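# pniflow

Psychoneuroimmune dynamics in endurance athletes: how dietary patterns,
psychological state and immune function co-evolve over a competitive year,
and whether an athlete's response to their diet can be predicted from
baseline characteristics. `pniflow` is an R package for studying these
questions on reproducible synthetic longitudinal cohorts with *planted*,
therefore known, structure: a psychology-to-immunity temporal lag, a serial
diet → psychology → cortisol → immunity mediation chain, and
resilience-dependent response trajectories. Because the ground truth is
planted, every stage of the analysis pipeline — cleaning, temporal
cross-validation, prediction, attribution, inference — can be validated
against it.

It is aimed at sports-science and psychoneuroimmunology researchers who
want a tested scaffold for longitudinal nutrition–psychology–immunity
analyses, and at methodologists who need calibrated synthetic panels to
benchmark such pipelines.

## What is inside

**Synthetic cohort generator.** 200 athletes in three dietary-pattern
groups (high-carbohydrate n = 68, high-protein n = 65, balanced n = 67),
24 bi-weekly time points, 52 features (12 psychological, 18 nutritional,
15 immunological, 7 performance). Group labels follow macronutrient rules
(high-carb: > 60% energy from carbohydrate, protein < 1.2 g/kg/day;
high-protein: ≥ 1.6 g/kg/day protein; balanced: 50–60% carbohydrate,
1.2–1.6 g/kg/day protein). Psychological change leads immune change by a
configurable lag (default 3 bi-weekly steps ≈ 1.5 months).

**Hybrid temporal/boosting predictor.** A stacked-LSTM temporal branch
(written from scratch in base R, with backpropagation through time and
Adam; gradients are verified against finite differences in the test suite)
processes each athlete's feature history

```
h_t = LSTM(x_t, h_{t-1})
```

while a gradient-boosting branch (xgboost) models static per-athlete
features. The two are fused by attention:

```
z = α₁ h_LSTM + α₂ h_XGBoost ,   αᵢ = softmax(W [h₁; h₂])
```

trained under an 80/20 athlete holdout with 5-fold forward-chaining
temporal cross-validation and a two-month gap between training and
validation windows (leakage is asserted in tests).

**Attribution.** A sampling-based Shapley estimator with exact local
accuracy (per-athlete attributions sum to prediction minus background
expectation), used to rank baseline predictors of dietary-pattern
response.

**Inference machinery.** Lagged cross-correlation scans with within-athlete
Fisher-z pooling; first canonical correlation between the psychological
and immune blocks; serial mediation by the product-of-coefficients
approach,

```
indirect(serial) = a₁ · a₂ · b₂ ,   proportion mediated = 100 · Σ indirect / c
```

with bias-corrected bootstrap confidence intervals; ARIMA(p, d, q) order
selection by AIC with a parsimony band; mixed-effects (random-intercept)
subgroup models; and onset / improvement-rate / plateau characterisation of
resilience-tertile response trajectories.

## Worked example

```r
library(pniflow)

spec  <- cohort_spec(seed = 7)      # default calibrated scenario
panel <- generate_cohort(spec)

summarize_change(panel, "fatigue")
#>   group        baseline_mean endpoint_mean  delta percent_change clinical_improvement_pct
#> 1 balanced              4.58          2.73 -1.85            40.4                     83.6
#> 2 high_carb             5.90          5.04 -0.863           14.6                     38.2
#> 3 high_protein          5.29          4.06 -1.23            23.2                     63.1

lag_correlation_scan(panel, "fatigue", "il6", max_lag = 6, seed = 7)
#> <lag_scan> fatigue leads il6: peak r = 0.719 at lag 3 steps (1.6 months)
```

The balanced group improves most (a 1.85-point fatigue reduction, with 84%
of its athletes reaching the ≥ 1-point minimal clinically important
difference), and fatigue changes lead IL-6 changes by the planted 3
bi-weekly steps. The serial mediation chain is recovered from simulated
chain data:

```r
chain <- simulate_mediation_data(n = 2000, a1 = 0.5, a2 = 0.6,
                                 b1 = 0.4, b2 = 0.4, cprime = 0.2,
                                 noise_sd = 0.3, seed = 7)
fit_mediation_serial(chain, n_boot = 1000, seed = 7)
#> <mediation_result> serial (x -> m1 -> m2 -> y)
#>    term            estimate      se   ci_lo   ci_hi
#>  1 a1               0.491   0.00651  0.478  0.503
#>  ...
#>  9 indirect_serial  0.112   0.00785  0.0981 0.129
#> proportion mediated: 58.7%  (n = 2000, 1000 bootstrap draws)
```

The serial indirect effect a₁a₂b₂ = 0.12 lies inside the bootstrap CI.
The whole pipeline (generate → degrade → clean → impute → split → train →
explain → mediate → lag-scan → subgroup reports) runs from one YAML
config:

```r
run_pipeline(system.file("extdata", "desk_scale.yaml", package = "pniflow"),
             "runs/demo")
```

or from the shell via the thin wrapper `inst/cli/pni`:

```sh
Rscript inst/cli/pni run --config inst/extdata/desk_scale.yaml --out runs/demo
```

Two profiles ship: `desk_scale.yaml` (shrunken model, 1000 bootstrap
draws; used by the tests) and `paper_scale.yaml` (full-size layer widths
and 500 boosting rounds).

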