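# filabicu

Deficit-accumulation frailty analysis for critically ill cohorts, built
around the **FI-Lab**: a frailty index computed from routine laboratory
tests and vital signs at ICU admission. The package is aimed at
biostatisticians and intensive-care researchers who want a fully testable,
simulation-backed version of the standard FI-Lab survival workflow —
scoring, cohort assembly, Cox/spline/Kaplan–Meier modelling and ROC
discrimination — without access to a credentialed EHR extract.

## The index and the models

For a registry of items (default: 33 — 20 blood tests, 4 arterial blood-gas
values, 6 urinalysis results, 3 vital signs), each item is dichotomized
against its clinical reference definition (0 = normal, 1 = deficit) and

```
FI-Lab = (number of deficits) / (number of measured items)  ∈ [0, 1]
```

Labs use the first value within −6 h to +24 h of ICU admission; vitals are
averaged over the first 24 h; stays missing more than 12 items are
ineligible. The association with 28-day, 90-day and ICU mortality is
estimated with Cox proportional-hazards models,

```
h(t | x) = h0(t) · exp( β · FI-Lab/0.1 + γ'z ),
```

reported per 0.1-unit increase and by tertiles (trend test via an ordinal
refit), with restricted-cubic-spline dose–response curves and a Wald
non-linearity test, Kaplan–Meier/log-rank comparison of tertiles, subgroup
and interaction analyses, and ROC discrimination (DeLong AUC variance and
paired tests, Youden-optimal cutoffs).

Because real ICU extracts are access-controlled, the package ships a
synthetic cohort generator (`sim_config()`, `generate_cohort()`) that
emits MIMIC-style stays / lab-events / vitals tables with *known* deficit
probabilities and hazard structure, so every stage is testable against
ground truth.

## Worked example

```r
library(filabicu)

tabs <- generate_cohort(sim_config(n_patients = 2000, seed = 1))
sc   <- compute_filab(tabs$lab_events, tabs$vitals,
                      stay_ids = tabs$stays$stay_id)
flt  <- apply_filters(tabs$stays, sc)
flt$log
#>               rule n_removed n_remaining
#> 1      repeat_stay        36        1964
#> 2     age_under_18        42        1922
#> 3    los_under_24h        37        1885
#> 4        pregnancy        46        1839
#> 5 missing_required        33        1806
#> 6 filab_ineligible        34        1772

co <- impute_covariates(drop_sparse_missing(flt$cohort)$cohort,
        columns = c("age", "respiratory_rate", "bicarbonate", "pao2_fio2",
                    "apsiii", "sofa", "apache_ii", "cci"))
co$filab_tertile <- assign_tertile(co$filab_score)

fit_cox(co, "mortality_28d", model = "model3")
#> Cox model: mortality_28d, FI-Lab per_0_1, model3 (n = 1763, events = 222)
#>          term    HR        95% CI      p
#>  .filab_per01 1.437 (1.237-1.670) <0.001
#>  ...
```

The first row is the headline estimate: each 0.1-unit increase in FI-Lab
multiplies the 28-day death hazard by ~1.44 in this simulated cohort (whose
generating value is 1.32; the interval covers it). The remaining rows are
the adjustment covariates, which are inert in the generator and correctly
hover around HR 1.

```r
fit_rcs(co, "mortality_28d")
#> Restricted cubic spline Cox model (mortality_28d), 4 knots
#> knots: 0.333, 0.452, 0.515, 0.625
#> reference (HR = 1): 0.485
#> p for non-linearity (Wald, 2 df): 0.511

km_logrank(co)
#> Kaplan-Meier (mortality_28d), groups: T1, T2, T3
#> log-rank chi-square = 14.968 (df = 2), p = 0.000562

roc_compare(co)
#> ROC analysis (mortality_28d)
#>   filab_score: AUC 0.590 (0.551-0.629), Youden cutoff 0.467 (sens 0.685, spec 0.447)
#>   sofa: AUC 0.495 (0.455-0.536), ...
#>   DeLong filab_score vs sofa: p = 0.000814
```

The generator's hazard is exactly log-linear in the score, so the spline
test correctly finds no curvature; the tertile survival curves separate
(log-rank p < 0.001); and FI-Lab discriminates 28-day death while the inert
severity-score comparators sit at AUC ≈ 0.5.

`run_pipeline(config, out_dir)` chains all of the above into one
reproducible run with CSV outputs, a Markdown report and a JSON manifest of
seeds, hashes and stage timings. See the methods vignette
(`vignettes/filab-methods.Rmd`) for the model assumptions, default
calibration and design decisions.

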