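check_binary_outcome <- function(outcome) {
  y <- as.integer(outcome)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("outcome must be binary 0/1 without missing values")
  if (sum(y) == 0L || sum(y) == length(y))
    stop("outcome has a single class; AUC is undefined")
  y
}

proc_roc <- function(score, y) {
  pROC::roc(response = y, predictor = as.numeric(score), levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' AUC with DeLong variance and confidence interval
#'
#' Area under the ROC curve via the midrank Mann-Whitney statistic, with the
#' nonparametric DeLong variance from per-observation placement components
#' and a normal-approximation confidence interval truncated to `[0, 1]`.
#'
#' @param score Numeric predictor (higher = more likely positive).
#' @param outcome Binary 0/1 outcome.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `var`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @examples
#' auc_delong(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc
#' @export
auc_delong <- function(score, outcome, conf_level = 0.95) {
  y <- check_binary_outcome(outcome)
  stopifnot(length(score) == length(y))
  r <- proc_roc(score, y)
  a <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = a, var = v,
       ci_low = max(0, a - z * sqrt(v)), ci_high = min(1, a + z * sqrt(v)),
       n_pos = sum(y), n_neg = sum(1 - y))
}

#' Optimal cutoff by the Youden index
#'
#' Scans the observed score values (plus `+Inf`) as cutoffs under the rule
#' "score >= cutoff predicts positive" and returns the cutoff maximizing
#' sensitivity + specificity - 1, ties broken toward the lower threshold.
#'
#' @param score Numeric predictor.
#' @param outcome Binary 0/1 outcome.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(score, outcome) {
  y <- check_binary_outcome(outcome)
  stopifnot(length(score) == length(y))
  cuts <- sort(unique(c(score, Inf)))
  pos <- score[y == 1L]; neg <- score[y == 0L]
  sens <- vapply(cuts, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(neg < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # lower threshold on ties
  list(cutoff = cuts[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two scores measured on the same subjects:
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov_ab)` with the DeLong
#' structural-component covariance and a two-sided normal p-value. A
#' degenerate variance of the difference (e.g. identical or rank-identical
#' scores) is reported as `p = 1` with `degenerate = TRUE`.
#'
#' @param score_a,score_b Numeric predictors on the same subjects.
#' @param outcome Binary 0/1 outcome.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_paired_test <- function(score_a, score_b, outcome) {
  y <- check_binary_outcome(outcome)
  stopifnot(length(score_a) == length(y), length(score_b) == length(y))
  ra <- proc_roc(score_a, y); rb <- proc_roc(score_b, y)
  aa <- as.numeric(pROC::auc(ra)); ab <- as.numeric(pROC::auc(rb))
  va <- suppressWarnings(as.numeric(pROC::var(ra, method = "delong")))
  vb <- suppressWarnings(as.numeric(pROC::var(rb, method = "delong")))
  cab <- suppressWarnings(as.numeric(pROC::cov(ra, rb, method = "delong")))
  var_diff <- va + vb - 2 * cab
  if (!is.finite(var_diff) || var_diff < 1e-14) {
    return(list(auc_a = aa, auc_b = ab, z = 0, p = 1, degenerate = TRUE))
  }
  res <- tryCatch(pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
                  error = function(e) NULL)
  z <- if (is.null(res)) NaN else as.numeric(res$statistic)
  p <- if (is.null(res)) NaN else as.numeric(res$p.value)
  degenerate <- !is.finite(z)
  if (degenerate) { z <- 0; p <- 1 }
  list(auc_a = aa, auc_b = ab, z = z, p = p, degenerate = degenerate)
}

#' ROC comparison of the FI-Lab against severity-score comparators
#'
#' Computes, for each named score column, the AUC for the binary outcome
#' with DeLong variance and confidence interval plus the Youden-optimal
#' cutoff, and pairwise DeLong tests of every comparator against the first
#' (reference) score.
#'
#' @param cohort Analysis table.
#' @param scores Character vector of score columns; the first is the
#'   reference (default FI-Lab vs SOFA and APACHE II).
#' @param outcome Outcome name as in [fit_cox()]; its event indicator is
#'   the ROC label.
#' @return A `filab_roc` object with `per_score` and `pairwise` data frames.
#' @export
roc_compare <- function(cohort, scores = c("filab_score", "sofa", "apache_ii"),
                        outcome = "mortality_28d") {
  oc <- outcome_columns(outcome)
  y <- check_binary_outcome(cohort[[oc["event"]]])
  per <- lapply(scores, function(sc) {
    v <- cohort[[sc]]
    if (is.null(v)) stop("score column '", sc, "' not in cohort")
    a <- auc_delong(v, y)
    yc <- youden_cutoff(v, y)
    data.frame(score = sc, auc = a$auc, var = a$var, ci_low = a$ci_low,
               ci_high = a$ci_high, cutoff = yc$cutoff,
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               stringsAsFactors = FALSE)
  })
  pair <- list()
  if (length(scores) > 1L) {
    for (sc in scores[-1L]) {
      t <- delong_paired_test(cohort[[scores[1L]]], cohort[[sc]], y)
      pair[[sc]] <- data.frame(score_a = scores[1L], score_b = sc,
                               auc_diff = t$auc_a - t$auc_b, z = t$z, p = t$p,
                               degenerate = t$degenerate,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(per_score = do.call(rbind, per),
                 pairwise = if (length(pair)) do.call(rbind, c(pair, make.row.names = FALSE)) else NULL,
                 outcome = outcome),
            class = "filab_roc")
}

#' @export
print.filab_roc <- function(x, ...) {
  cat(sprintf("ROC analysis (%s)\n", x$outcome))
  p <- x$per_score
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s: AUC %.3f (%.3f-%.3f), Youden cutoff %.3f (sens %.3f, spec %.3f)\n",
                p$score[i], p$auc[i], p$ci_low[i], p$ci_high[i], p$cutoff[i],
                p$sensitivity[i], p$specificity[i]))
  if (!is.null(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  DeLong %s vs %s: p = %s\n", x$pairwise$score_a[i],
                  x$pairwise$score_b[i],
                  format.pval(x$pairwise$p[i], digits = 3, eps = 1e-4)))
  invisible(x)
}
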