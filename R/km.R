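#' Kaplan-Meier curves by FI-Lab group with a log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' comparing them (observed-minus-expected events over the pooled event
#' times with hypergeometric variance, `groups - 1` degrees of freedom).
#' With a single group the curve is still returned and the test is `NA`.
#'
#' @param cohort Analysis table.
#' @param group_col Grouping column (default `"filab_tertile"`).
#' @param outcome Outcome name as in [fit_cox()].
#' @return A `filab_km` object: `curves` (`group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(cohort, group_col = "filab_tertile",
                       outcome = "mortality_28d") {
  oc <- outcome_columns(outcome)
  g <- droplevels(factor(cohort[[group_col]]))
  if (any(is.na(g))) stop("missing values in grouping column '", group_col, "'")
  time <- cohort[[oc["time"]]]; event <- cohort[[oc["event"]]]
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  if (nlevels(g) > 1L) {
    strata_grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  } else {
    strata_grp <- rep(levels(g), length(sf$time))
  }
  curves <- data.frame(group = strata_grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  chisq <- df <- p <- NA_real_
  if (nlevels(g) > 1L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    chisq <- sd$chisq
    df <- nlevels(g) - 1L
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  structure(list(curves = curves, groups = levels(g), chisq = chisq,
                 df = df, p = p, outcome = outcome),
            class = "filab_km")
}

#' @export
print.filab_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier (%s), groups: %s\n", x$outcome,
              paste(x$groups, collapse = ", ")))
  if (!is.na(x$chisq))
    cat(sprintf("log-rank chi-square = %.3f (df = %d), p = %s\n", x$chisq,
                x$df, format.pval(x$p, digits = 3, eps = 1e-4)))
  else cat("single group: log-rank test undefined\n")
  invisible(x)
}

#' Survival probability of a fitted curve at given times
#'
#' Step-function lookup of the product-limit estimate for one group.
#'
#' @param km A `filab_km` object.
#' @param group Group label.
#' @param times Numeric times (days).
#' @return Numeric survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(km, group, times) {
  cv <- km$curves[km$curves$group == group, ]
  vapply(times, function(t) {
    i <- which(cv$time <= t)
    if (!length(i)) 1 else cv$surv[max(i)]
  }, numeric(1))
}
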