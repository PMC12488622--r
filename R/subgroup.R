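#' Default subgroup stratifiers
#'
#' The conventional ICU dichotomizations: age at 60 years, SOFA at 5, and
#' the binary flags sex, race (white vs non-white), sepsis, mechanical
#' ventilation and heart failure. Each entry names the stratifier, a
#' function of the cohort returning a two-level factor, and the adjustment
#' covariates that must be dropped inside its strata (a stratifier cannot
#' adjust for itself).
#'
#' @return Named list of stratifier definitions.
#' @export
default_stratifiers <- function() {
  list(
    age = list(split = function(d) factor(ifelse(d$age >= 60, ">=60", "<60"),
                                          levels = c("<60", ">=60")),
               drop = "age"),
    sex = list(split = function(d) factor(d$sex), drop = "sex"),
    race = list(split = function(d) factor(d$race), drop = "race"),
    sepsis = list(split = function(d) factor(ifelse(d$sepsis == 1, "yes", "no"),
                                             levels = c("no", "yes")),
                  drop = "sepsis"),
    mv = list(split = function(d) factor(ifelse(d$mv == 1, "yes", "no"),
                                         levels = c("no", "yes")),
              drop = "mv"),
    heart_failure = list(split = function(d) factor(ifelse(d$heart_failure == 1,
                                                           "yes", "no"),
                                                    levels = c("no", "yes")),
                         drop = "heart_failure"),
    sofa = list(split = function(d) factor(ifelse(d$sofa >= 5, ">=5", "<5"),
                                           levels = c("<5", ">=5")),
                drop = "sofa")
  )
}

#' Stratified and interaction analysis of the FI-Lab effect
#'
#' For each stratifier, fits the adjusted Cox model of the outcome on the
#' FI-Lab (per 0.1 unit) separately within each stratum, and obtains the
#' per-variable interaction p-value from the full-cohort model with an
#' exposure-by-stratifier product term (Wald test). Strata with no events
#' or a constant exposure are reported as non-estimable rather than failing
#' the whole analysis.
#'
#' @param cohort Analysis table with `filab_score` and covariates.
#' @param outcome Outcome name as in [fit_cox()].
#' @param stratifiers Named list as produced by [default_stratifiers()].
#' @param covariates Adjustment set (default model 3); the stratifying
#'   covariate is dropped within its own strata and interaction model.
#' @return A `filab_subgroups` data frame: `variable`, `level`, `n`,
#'   `n_events`, `hr`, `ci_low`, `ci_high`, `p`, `p_interaction`
#'   (repeated across the variable's rows), `estimable`.
#' @export
subgroup_analysis <- function(cohort, outcome = "mortality_28d",
                              stratifiers = default_stratifiers(),
                              covariates = model_covariates()$model3) {
  oc <- outcome_columns(outcome)
  rows <- list()
  for (vn in names(stratifiers)) {
    sdef <- stratifiers[[vn]]
    grp <- droplevels(sdef$split(cohort))
    covs <- setdiff(covariates, sdef$drop)
    # interaction p from the full-cohort product-term model
    p_int <- NA_real_
    if (nlevels(grp) >= 2L) {
      dat <- cox_rhs_data(cohort, covs)
      dat$.filab_per01 <- dat$filab_score / 0.1
      dat$.strat <- grp
      fml <- stats::reformulate(c(".filab_per01 * .strat", covs),
                                response = sprintf("survival::Surv(%s, %s)",
                                                   oc["time"], oc["event"]))
      p_int <- tryCatch({
        fit <- survival::coxph(fml, data = dat, ties = "efron")
        co <- summary(fit)$coefficients
        ia <- grep("^\\.filab_per01:", rownames(co))
        if (length(ia) == 1L) co[ia, "Pr(>|z|)"] else {
          b <- stats::coef(fit)[ia]; V <- stats::vcov(fit)[ia, ia]
          stats::pchisq(drop(t(b) %*% solve(V, b)), length(ia),
                        lower.tail = FALSE)
        }
      }, error = function(e) NA_real_)
    }
    for (lv in levels(grp)) {
      sub <- cohort[which(grp == lv), , drop = FALSE]
      nev <- sum(sub[[oc["event"]]], na.rm = TRUE)
      est <- data.frame(variable = vn, level = lv, n = nrow(sub),
                        n_events = nev, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        p_interaction = p_int, estimable = FALSE,
                        stringsAsFactors = FALSE)
      if (nev > 0L && length(unique(sub$filab_score)) > 1L) {
        fit <- tryCatch(fit_cox(sub, outcome, exposure = "per_0_1",
                                covariates = covs),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          tr <- fit$terms[fit$terms$term == ".filab_per01", ]
          if (nrow(tr) == 1L && is.finite(tr$hr)) {
            est[c("hr", "ci_low", "ci_high", "p")] <-
              tr[c("hr", "ci_low", "ci_high", "p")]
            est$estimable <- TRUE
          }
        }
      }
      rows[[length(rows) + 1L]] <- est
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("filab_subgroups", "data.frame")
  out
}
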