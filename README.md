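# survmature

Survival-extrapolation accuracy under artificial database locks.

When lifetime survival must be estimated from right-censored data — the
situation of every health-economic evaluation built on a trial or registry
snapshot — a parametric model is fitted and its curve extrapolated. How
wrong that extrapolation is depends on the *maturity* of the data at the
cut-off: the maximum follow-up, the percentage censored, and the number of
events. `survmature` quantifies that relationship by simulation for cohorts
with the structure of multiple-myeloma trials and registries: staggered
enrollment over calendar years, median overall survival of a few years, a
rising-then-falling hazard, and 100–650 subjects.

The pipeline: generate a cohort with known truth → impose **database
locks** at increasing maximum follow-up (default 3, 6, 8, 10, 13 years) →
fit the 16-model roster (exponential, Weibull, Gompertz, gamma,
log-logistic, lognormal, generalized gamma, plus Royston–Parmar natural
cubic spline models on the hazard, odds and normal scales with 1–3 internal
knots) by censored maximum likelihood → score each fit by its signed
restricted-mean-survival-time error

$$\Delta(\tau) = \int_0^\tau S_{\text{model}}(u)\,du - \int_0^\tau \hat S_{\text{KM}}(u)\,du,$$

against the Kaplan–Meier estimate of the long-follow-up data, together with
a 35-year lifetime RMST and the conditional RMST error
$\int_{t_0}^{\tau} S \,/\, S(t_0)$ restricted to the extrapolated region
beyond the lock at $t_0$. Models are selected per lock by lowest AIC and
lowest BIC with a fewest-parameters tie-break.

All model fitting (censored MLE for the seven families and the spline
models) is implemented in the package; Kaplan–Meier estimation is delegated
to the `survival` package.

## Worked example

```r
library(survmature)

# a registry-style cohort: 552 subjects enrolled 2005-2010, true hazard
# rises then falls, median OS ~3.1 years
spec <- cohort_spec(552, 2005, 2010, mm_hazard_presets()$piecewise,
                    label = "registry", seed = 1)
cohort <- generate_cohort(spec)

# lock the database at 3 years of maximum follow-up, and keep a
# long-follow-up reference (19 years: every subject followed >= 14)
locked <- lock_grid(cohort, c(3))[["<3y"]]
reference <- apply_lock(cohort, 2005 + 19, label = "reference")
censoring_summary(locked)
#> $pct_censored      $n_events      $n_subjects
#> [1] 79.941         [1] 68         [1] 339

fit <- fit_parametric("weibull", locked)
fit
#> Parametric survival fit: weibull (converged)
#>  shape  scale
#> 1.2230 5.0084
#> logLik -192.773  AIC 389.55  BIC 397.20  (n = 339, events = 68)
rmst(fit, 35)
#> [1] 4.688853

rec <- evaluate_lock(reference, locked, horizon = 14)
attr(rec, "km_rmst")
#> [1] 5.225386
rec[grepl("AIC|BIC", rec$selected_by),
    c("model", "rmst", "rmst_error", "cond_rmst_error", "selected_by")]
#>               model     rmst rmst_error cond_rmst_error selected_by
#> 3          gompertz 3.059834  -2.165552       -4.075199         BIC
#> 16 spline_normal_3k 3.132839  -2.092547       -3.772628         AIC
summary(abs(rec$rmst_error[rec$converged]))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.05146 0.59018 1.27704 1.31731 2.05608 2.45111
```

At three years of follow-up, 80% of subjects are censored on 68 events, and
the roster misjudges the 14-year RMST by a median of 1.3 years (up to 2.5),
with the conditional error in the extrapolated region larger still. Locks
at 8+ years shrink the median error to a few tenths of a year —
`run_experiment()` sweeps the whole grid and `plot_rmst_error()` draws the
error-vs-censoring scatter.

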