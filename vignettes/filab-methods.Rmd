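---
title: "Methods: the FI-Lab frailty index and its survival analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the FI-Lab frailty index and its survival analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The index

The FI-Lab is a deficit-accumulation frailty index computed from routine
measurements at ICU admission. A registry defines the scoreable items — by
default 33 of them: 20 blood tests, 4 arterial blood-gas values, 6 urinalysis
results and 3 vital signs (systolic and diastolic blood pressure, heart
rate). Each item is dichotomized: a numeric value inside its clinical
reference interval scores 0, outside scores 1; a categorical urinalysis
result scores 1 when it falls in the item's abnormal-category set. The index
is

$$\mathrm{FI\text{-}Lab} = \frac{\text{number of deficits}}{\text{number of measured items}} \in [0, 1].$$

Laboratory items use the first value charted between 6 hours before and 24
hours after ICU admission (both endpoints included); vital signs are averaged
over the first 24 hours. A stay missing more than 12 items is ineligible and
receives no score.

Several conventions here are genuine design choices, because the field's
descriptions leave them open; they are all configurable:

* **Denominator.** We divide by the number of *measured* items, the standard
  deficit-accumulation practice when a bounded amount of missingness is
  tolerated; dividing by a fixed 33 would push scores of missing-heavy stays
  below their attainable range. `compute_filab(denominator = "fixed")`
  switches to the fixed denominator.
* **Boundary values.** The reference interval is closed: a value exactly at a
  limit is normal, matching conventional laboratory flagging.
* **Multiple lab values in window.** The chronologically first is used (ties
  broken by input order); it best represents admission state, and averaging
  is reserved for vitals where it is the stated convention.
* **Window endpoints** are inclusive — the least surprising reading of
  "within".
* **Urinalysis coding**: any reported positive/trace/graded category counts
  as a deficit; "negative" does not.
* **Reference intervals.** The shipped registry uses standard adult clinical
  reference intervals. They are deliberately ordinary and fully
  user-overridable (`load_registry()` accepts any CSV in the same schema);
  any site-specific ranges can be dropped in without code changes.

Tertile labels follow the half-open printed convention: T1 is score
$< c_1$, T2 is $[c_1, c_2)$, T3 is $\ge c_2$, with cutpoints either fixed
(e.g. 0.43/0.54) or cohort-empirical.

## The synthetic cohort generator

Real credentialed ICU extracts cannot ship with a package, so every
downstream stage is developed and tested against a simulator with fully
known structure (`sim_config()` / `generate_cohort()`). Per stay, each
registry item is independently missing with its configured probability and,
when present, abnormal with its configured probability; numeric values are
placed uniformly inside the reference interval when normal and 10–50% of the
interval width beyond a randomly chosen bound when abnormal (magnitude is
irrelevant to a dichotomized score, so only sidedness matters). Lab
charttimes are uniform on [−6 h, +24 h], vitals on [0, 24 h]; a configurable
fraction of lab records can be displaced outside the window to exercise
window filtering. An optional per-stay latent factor on the logit scale
(`frailty_sd`) induces positive inter-item correlation; the default keeps
items independent, and neither mode is claimed to match any particular real
cohort's dependence structure.

Survival is exponential with log hazard
$\beta_{0.1} \cdot (\mathrm{FI\text{-}Lab}/0.1) + \sum_j \gamma_j x_j$:
a constant baseline hazard is all a Cox analysis needs (Cox estimation is
baseline-agnostic, and the exponential gives closed-form oracles such as
events/person-time rate ratios). The 28- and 90-day outcomes are
administratively censored at their horizons; ICU death means death before an
independent exponential discharge clock — the simplest mechanism that makes
ICU mortality rarer than 28-day mortality.

Default conditions (chosen once, as the study conditions the package
emulates): per-item abnormality probability 0.48, putting the mean score
near 0.48 — consistent with tertile boundaries near 0.43 and 0.54; per-item
missingness 2%; true hazard ratio 1.32 per 0.1 unit; baseline hazard
0.0013/day, calibrated so the default effect size yields ≈13.2% 28-day
mortality; discharge rate $\log 2 / 2.8$ per day (median ICU stay 2.8 days);
PaO~2~/FiO~2~ missing in 5% of stays (the one covariate routed to
imputation) and APSIII in 0.5% (routed to complete-case removal); 2% of
stays violating each inclusion rule. Covariates (demographics at realistic
ICU-asthma prevalences, severity scores, comorbidity and intervention flags)
default to *zero* hazard effect: they are inert adjustment columns, and
parameter-recovery experiments need known structure, not realism. Nonzero
`covariate_effects` are switches for calibration experiments.

What the generator does **not** emulate: real covariate-deficit dependence,
unit systems and itemid vocabularies, informative censoring, treatment
effects, or non-constant baseline hazards. Passing tests therefore
demonstrate the pipeline's correctness and calibration under a known model,
not the clinical validity of any particular cohort's estimates.

## Cohort assembly

`apply_filters()` applies the exclusion cascade in a fixed audited order —
repeat ICU stays, age < 18, ICU stay < 24 h, pregnancy, missing required
first-day fields (respiratory rate, bicarbonate, glucocorticoid,
montelukast), FI-Lab ineligibility (> 12 missing items) — logging each
step's removals, so the order-dependent counts are explicit. The cascade is
idempotent.

Variables with missingness below 1% get complete-case handling
(`drop_sparse_missing()`); the published phrasing ("directly excluded
variables with missing values < 1%") is ambiguous between dropping rows and
dropping columns, so both are implemented behind `action =`, with rows as
the default since the same variables appear in later models. Remaining
numeric missingness is imputed by `impute_covariates()`: round-robin chained
equations where each incomplete column is regressed on all others with a
closed-form ridge estimator (penalty 10^-3 on the standardized scale — a
deterministic analogue of a Bayesian ridge posterior mean), cycling until
the largest cell change falls below 10^-3 or 10 rounds. Observed cells are
never altered and the result is deterministic. Multicollinearity is
screened by `vif_screen()`, the closed form $1/(1-R^2_j)$, flagging
VIF > 2; perfect collinearity reports an infinite VIF rather than failing.

## Survival models

`fit_cox()` fits partial-likelihood Cox models with Efron ties (appropriate
for day-resolution data), Wald intervals and p-values. Exposure codings:
continuous per 0.1 FI-Lab units, or tertiles with T1 as reference (printed
as HR 1 with an empty interval). The tertile trend p comes from refitting
with the tertile index 0/1/2 as one ordinal term — a deliberate choice over
a Wald contrast on the categorical fit, and recorded as such. Adjustment
sets are nested and configurable; the default allocation (model 1
demographics; model 2 + severity scores; model 3 + comorbidities and
interventions) is the conventional cascade, since published model
compositions are rarely enumerated, and every fit records the set it used.

`fit_rcs()` models the score with a restricted cubic spline — the
truncated-power basis whose first column is linear and whose remaining
columns are the curvature terms, so the Wald test that those coefficients
vanish is exactly the non-linearity test. Knots default to 4 at the
5/35/65/95% quantiles (the standard placements). The curve is centered at a
reference value, cohort median by default (configurable, since a published
HR = 1 anchor near the cohort centre is consistent with a median reference
but rarely stated); the hazard ratio at the reference is exactly 1 by
construction, and pointwise bands come from the delta method on the spline
coefficients.

`km_logrank()` wraps the product-limit estimator and the log-rank test
(hypergeometric observed-minus-expected over pooled event times). A single
group returns its curve with an undefined test rather than an error.
`subgroup_analysis()` refits the adjusted model inside each stratum of the
conventional ICU dichotomizations (age 60, SOFA 5, sex, race, sepsis,
mechanical ventilation, heart failure), dropping the stratifier from its own
adjustment set, and takes the interaction p from the full-cohort
product-term model; zero-event strata are flagged non-estimable, not fatal.

## Discrimination

`auc_delong()`, `youden_cutoff()`, `delong_paired_test()` and the
`roc_compare()` wrapper give the AUC with DeLong variance and normal
confidence interval, the Youden-optimal cutoff, and the paired DeLong
z-test for correlated AUCs. Cutoffs are scanned over observed score values
(plus +Inf) under the rule "score ≥ cutoff predicts positive", ties broken
toward the lower threshold — a fixed, reproducible convention (midpoint
thresholds, as some ROC packages use, shift the reported cutoff without
changing the index). A degenerate variance of the AUC difference (identical
or rank-identical scores) reports p = 1 with a flag instead of dividing by
zero. Note that published "optimal cutoffs" for a 0–1 frailty score are not
always on the raw score scale; the package reports the raw-scale cutoff and
makes no claim about other scales.

## Numerical and degenerate-input policy

Configuration errors name the offending field. Scoring errors name the stay
and item. Zero-event outcomes and constant exposures are refused with
explicit messages; degenerate strata and collinear columns are flagged in
output rather than raised. All randomness flows from a single integer seed;
identical configurations give bit-identical tables, and the pipeline
manifest records file hashes so end-to-end determinism is checkable.

## Problem sizes used in the shipped checks

The test suite and acceptance script choose sizes where the statistical
properties are decisive at desk scale: parameter recovery at n = 20,000
stays per outcome; type-I-error calibration of the non-linearity and
interaction tests over 100 replicates (n = 10,000 and 2,000); null CI
coverage over 200 replicates at n = 400; DeLong size over 400 replicates at
n = 500; law-of-large-numbers checks at n = 50,000; exact oracles
(pair-counting AUC, hypergeometric log-rank, exhaustive Fisher, closed-form
VIF) on 8–20-subject fixtures.

## Known limitations

Deficit independence (or a single latent factor) is a simplification; real
laboratory panels have block correlation. The ICU-discharge clock is
independent of the death process, so discharge is non-informative censoring
by construction. The imputer handles numeric covariates only. No
proportional-hazards diagnostics beyond what `survival` offers on the
underlying fits, no competing-risks estimators, and no time-dependent ROC —
all deliberate scope boundaries.
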