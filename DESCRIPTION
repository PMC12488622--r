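Package: filabicu
Title: Laboratory Frailty Index (FI-Lab) Survival Analysis for ICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deficit-accumulation frailty analysis of critically ill
    cohorts using a 33-item laboratory frailty index (FI-Lab): a synthetic
    ICU cohort simulator with known hazard structure, FI-Lab scoring from
    long-format lab and vital-sign records against an editable reference-range
    registry, inclusion/exclusion cascades with chained ridge imputation and
    VIF screening, Cox proportional-hazards models (continuous per-0.1-unit
    and tertile codings with trend tests), restricted cubic spline dose-response
    curves with non-linearity tests, Kaplan-Meier/log-rank analysis, subgroup
    and interaction analysis, and ROC discrimination with Youden cutoffs and
    DeLong comparisons of correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
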