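#' Baseline characteristics table with between-group tests
#'
#' Builds a Table-1-style summary by group. Continuous variables are routed
#' by a Shapiro-Wilk normality check (at `alpha_normal`, on a subsample of
#' at most 5000 per group): normal variables are reported as mean (SD) and
#' compared by one-way ANOVA, non-normal ones as median (IQR) and compared
#' by the Kruskal-Wallis rank-sum test. Categorical variables are reported
#' as n (%) and compared by the chi-square test, switching to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param cohort Analysis table.
#' @param group_col Grouping column (e.g. `"filab_tertile"`).
#' @param variables Columns to summarize; defaults to every column except
#'   identifiers, times and the grouping itself.
#' @param alpha_normal Shapiro-Wilk alpha for the normality routing
#'   (default 0.05).
#' @return Data frame: `variable`, `type`, `test`, one summary column per
#'   group, `p`.
#' @export
summarize_baseline <- function(cohort, group_col = "filab_tertile",
                               variables = NULL, alpha_normal = 0.05) {
  g <- cohort[[group_col]]  # declared-but-empty factor levels are an error
  if (!is.factor(g)) g <- factor(g)
  if (any(is.na(g))) stop("missing values in grouping column")
  if (any(table(g) == 0L))
    stop("empty group: ", paste(names(which(table(g) == 0L)), collapse = ", "))
  if (is.null(variables))
    variables <- setdiff(names(cohort),
                         c(group_col, "stay_id", "admission_time",
                           grep("^time_", names(cohort), value = TRUE)))
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    is_cat <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && length(unique(stats::na.omit(x))) <= 2L)
    if (is_cat) rows[[v]] <- summarize_categorical(x, g, v)
    else rows[[v]] <- summarize_continuous(x, g, v, alpha_normal)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summarize_continuous <- function(x, g, name, alpha_normal) {
  normal <- all(vapply(levels(g), function(lv) {
    xi <- stats::na.omit(x[g == lv])
    if (length(xi) < 3L || length(unique(xi)) == 1L) return(FALSE)
    if (length(xi) > 5000L) xi <- xi[seq_len(5000L)]
    stats::shapiro.test(xi)$p.value > alpha_normal
  }, logical(1)))
  if (normal) {
    summ <- vapply(levels(g), function(lv) {
      xi <- stats::na.omit(x[g == lv])
      sprintf("%.1f (%.1f)", mean(xi), stats::sd(xi))
    }, character(1))
    p <- if (nlevels(g) > 1L)
      summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1] else NA_real_
    test <- "anova"
  } else {
    summ <- vapply(levels(g), function(lv) {
      xi <- stats::na.omit(x[g == lv])
      q <- stats::quantile(xi, c(0.25, 0.5, 0.75))
      sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
    }, character(1))
    p <- if (nlevels(g) > 1L) stats::kruskal.test(x, g)$p.value else NA_real_
    test <- "kruskal"
  }
  build_row(name, if (normal) "mean_sd" else "median_iqr", test, summ, p, levels(g))
}

summarize_categorical <- function(x, g, name) {
  x <- factor(x)
  tab <- table(x, g)
  summ <- vapply(levels(g), function(lv) {
    n <- tab[, lv]
    top <- if (nlevels(x) == 2L) nlevels(x) else which.max(rowSums(tab))
    sprintf("%d (%.1f%%)", n[top], 100 * n[top] / max(sum(n), 1L))
  }, character(1))
  p <- NA_real_; test <- "chisq"
  if (nlevels(g) > 1L && nrow(tab) > 1L) {
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    # expected counts at or below 5 count as small -> exact test
    if (any(cs$expected <= 5)) {
      test <- "fisher"
      p <- stats::fisher.test(tab)$p.value
    } else p <- cs$p.value
  }
  build_row(name, "n_pct", test, summ, p, levels(g))
}

build_row <- function(name, type, test, summ, p, group_levels) {
  row <- data.frame(variable = name, type = type, test = test,
                    stringsAsFactors = FALSE)
  for (i in seq_along(group_levels)) row[[group_levels[i]]] <- summ[i]
  row$p <- p
  row
}
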