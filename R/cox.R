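outcome_columns <- function(outcome) {
  switch(outcome,
         mortality_28d = c(time = "time_28d", event = "death_28d"),
         mortality_icu = c(time = "time_icu", event = "death_icu"),
         mortality_90d = c(time = "time_90d", event = "death_90d"),
         stop("unknown outcome '", outcome, "'"))
}

#' Nested covariate sets for the adjusted Cox models
#'
#' The adjustment cascade is conventional and configurable: the unadjusted
#' model has no covariates; model 1 adds demographics (age, sex, race);
#' model 2 adds severity scores (SOFA, APSIII, CCI); model 3 adds
#' comorbidities and interventions. Every fitted object records the set it
#' used.
#'
#' @return Named list of covariate-name vectors
#'   (`unadjusted`, `model1`, `model2`, `model3`).
#' @export
model_covariates <- function() {
  m1 <- c("age", "sex", "race")
  m2 <- c(m1, "sofa", "apsiii", "cci")
  m3 <- c(m2, "heart_failure", "hypertension", "diabetes", "copd", "aeba",
          "cardiac_shock", "sepsis", "mv", "vasopressor", "glucocorticoid",
          "montelukast")
  list(unadjusted = character(0), model1 = m1, model2 = m2, model3 = m3)
}

cox_rhs_data <- function(cohort, covariates) {
  dat <- cohort
  for (v in covariates) {
    if (is.null(dat[[v]])) stop("covariate '", v, "' not in cohort")
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  }
  dat
}

#' Cox proportional-hazards model of mortality on the FI-Lab
#'
#' Fits the partial-likelihood Cox model of a mortality outcome on the
#' FI-Lab, either as a continuous exposure scaled so one unit equals 0.1
#' score points, or as tertiles with the lowest tertile as reference. Four
#' nested adjustment levels are available (see [model_covariates()]). For
#' the tertile coding a trend p-value is obtained by refitting with the
#' tertile index (0, 1, 2) as a single ordinal term.
#'
#' @param cohort Analysis table with `filab_score`, outcome columns and any
#'   adjustment covariates.
#' @param outcome One of `"mortality_28d"`, `"mortality_icu"`,
#'   `"mortality_90d"`.
#' @param exposure `"per_0_1"` (default) or `"tertiles"`.
#' @param model Adjustment level: `"unadjusted"`, `"model1"`, `"model2"`,
#'   `"model3"`.
#' @param covariates Optional explicit covariate vector overriding `model`.
#' @param cutpoints Tertile cutpoints (pair, or `"empirical"`); used only
#'   for the tertile coding and ignored if the cohort already has a
#'   `filab_tertile` column.
#' @param ties Ties method for the partial likelihood (`"efron"` default).
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return A `filab_cox` object: data frame of per-term hazard ratios with
#'   confidence limits and p-values (reference tertile printed as HR 1 with
#'   empty interval), plus `n`, `n_events`, `loglik`, `p_trend` (tertile
#'   coding only) and the model metadata.
#' @examples
#' tabs <- generate_cohort(sim_config(n_patients = 400, seed = 8))
#' cohort <- cbind(tabs$stays, filab_score = tabs$truth$true_score)
#' fit_cox(cohort, "mortality_28d", model = "unadjusted")
#' @export
fit_cox <- function(cohort, outcome = "mortality_28d",
                    exposure = c("per_0_1", "tertiles"),
                    model = "model3", covariates = NULL,
                    cutpoints = "empirical",
                    ties = c("efron", "breslow"), conf_level = 0.95) {
  exposure <- match.arg(exposure)
  ties <- match.arg(ties)
  oc <- outcome_columns(outcome)
  if (is.null(covariates)) {
    sets <- model_covariates()
    if (!model %in% names(sets)) stop("unknown model '", model, "'")
    covariates <- sets[[model]]
  }
  dat <- cox_rhs_data(cohort, covariates)
  n_events <- sum(dat[[oc["event"]]])
  if (n_events == 0L) stop("no events for outcome '", outcome, "'")
  if (exposure == "per_0_1") {
    dat$.filab_per01 <- dat$filab_score / 0.1
    if (stats::var(dat$.filab_per01, na.rm = TRUE) == 0)
      stop("degenerate exposure: FI-Lab is constant in this cohort")
    exp_terms <- ".filab_per01"
  } else {
    if (is.null(dat$filab_tertile))
      dat$filab_tertile <- assign_tertile(dat$filab_score, cutpoints)
    dat$filab_tertile <- droplevels(factor(dat$filab_tertile,
                                           levels = c("T1", "T2", "T3")))
    if (nlevels(dat$filab_tertile) < 2L)
      stop("degenerate exposure: a single tertile is occupied")
    exp_terms <- "filab_tertile"
  }
  fml <- stats::reformulate(c(exp_terms, covariates),
                            response = sprintf("survival::Surv(%s, %s)",
                                               oc["time"], oc["event"]))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(term = rownames(co),
                      hr = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + z * co[, "se(coef)"]),
                      p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  p_trend <- NA_real_
  if (exposure == "tertiles") {
    terms$term <- sub("^filab_tertile", "", terms$term)
    ref <- data.frame(term = levels(dat$filab_tertile)[1L], hr = 1,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    keep <- terms$term %in% levels(dat$filab_tertile)
    terms <- rbind(ref, terms[keep, ], terms[!keep, ])
    dat$.tert_idx <- as.integer(dat$filab_tertile) - 1L
    fml_tr <- stats::reformulate(c(".tert_idx", covariates),
                                 response = sprintf("survival::Surv(%s, %s)",
                                                    oc["time"], oc["event"]))
    tr <- survival::coxph(fml_tr, data = dat, ties = ties)
    p_trend <- summary(tr)$coefficients[".tert_idx", "Pr(>|z|)"]
  }
  structure(list(terms = terms, n = fit$n, n_events = fit$nevent,
                 loglik = fit$loglik[length(fit$loglik)], p_trend = p_trend,
                 outcome = outcome, exposure = exposure, model = model,
                 covariates = covariates, conf_level = conf_level,
                 ties = ties, coxph = fit),
            class = "filab_cox")
}

#' @export
print.filab_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model: %s, FI-Lab %s, %s (n = %d, events = %d)\n",
              x$outcome, x$exposure, x$model, x$n, x$n_events))
  t <- x$terms
  ci <- ifelse(is.na(t$ci_low), "(ref)",
               sprintf("(%.*f-%.*f)", digits, t$ci_low, digits, t$ci_high))
  out <- data.frame(term = t$term,
                    HR = sprintf("%.*f", digits, t$hr),
                    `95% CI` = ci,
                    p = ifelse(is.na(t$p), "",
                               format.pval(t$p, digits = 2, eps = 1e-3)),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  if (!is.na(x$p_trend))
    cat("p for trend:", format.pval(x$p_trend, digits = 2, eps = 1e-3), "\n")
  invisible(x)
}

#' @export
summary.filab_cox <- function(object, ...) object$terms

#' @export
coef.filab_cox <- function(object, ...) stats::coef(object$coxph)
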