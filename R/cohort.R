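#' Apply the inclusion/exclusion cascade
#'
#' Removes stays in a fixed, audited order: non-first ICU stays; age under
#' 18; ICU length of stay under 24 h; pregnancy; missing respiratory rate,
#' bicarbonate, glucocorticoid or montelukast; and FI-Lab ineligibility
#' (more than 12 unmeasured items). Each step is logged with the number
#' removed and remaining, so the cascade is auditable and order-dependent
#' counts are explicit.
#'
#' @param stays Stays table (one row per ICU stay).
#' @param filab_results FI-Lab results from [compute_filab()]; every stay
#'   must have a row.
#' @return List with `cohort` (analysis-ready stays joined with their FI-Lab
#'   columns) and `log` (data frame `rule`, `n_removed`, `n_remaining`).
#' @export
apply_filters <- function(stays, filab_results) {
  idx <- match(as.character(stays$stay_id), as.character(filab_results$stay_id))
  if (anyNA(idx))
    stop("stays without a FI-Lab result: ",
         paste(utils::head(stays$stay_id[is.na(idx)], 5), collapse = ", "))
  fl <- filab_results[idx, c("n_measured", "n_missing", "n_deficits",
                             "score", "eligible")]
  names(fl) <- paste0("filab_", c("n_measured", "n_missing", "n_deficits",
                                  "score", "eligible"))
  cur <- cbind(stays, fl, row.names = NULL)

  req <- c("respiratory_rate", "bicarbonate", "glucocorticoid", "montelukast")
  rules <- list(
    repeat_stay = function(d) !is.na(d$is_first_icu_stay) & d$is_first_icu_stay == 0,
    age_under_18 = function(d) !is.na(d$age) & d$age < 18,
    los_under_24h = function(d) !is.na(d$icu_los) & d$icu_los < 1,
    pregnancy = function(d) !is.na(d$pregnant) & d$pregnant == 1,
    missing_required = function(d) Reduce(`|`, lapply(req, function(cc) is.na(d[[cc]]))),
    filab_ineligible = function(d) !d$filab_eligible
  )
  log <- data.frame(rule = names(rules), n_removed = NA_integer_,
                    n_remaining = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(rules)) {
    drop <- rules[[k]](cur)
    log$n_removed[k] <- sum(drop)
    cur <- cur[!drop, , drop = FALSE]
    log$n_remaining[k] <- nrow(cur)
  }
  rownames(cur) <- NULL
  list(cohort = cur, log = log)
}

#' Complete-case handling for variables with very sparse missingness
#'
#' Variables whose missingness proportion is below `threshold` (default 1%)
#' get complete-case treatment: rows missing them are removed (`action =
#' "rows"`, the default) or the whole column is dropped (`action =
#' "columns"`). Variables at or above the threshold are left untouched and
#' routed to [impute_covariates()].
#'
#' @param cohort Analysis table.
#' @param threshold Missingness proportion below which a variable is handled
#'   here, in `(0, 1)`.
#' @param action `"rows"` or `"columns"`.
#' @return List with `cohort` and a `report` data frame (`variable`,
#'   `n_missing`, `frac_missing`, `handled`).
#' @export
drop_sparse_missing <- function(cohort, threshold = 0.01,
                                action = c("rows", "columns")) {
  action <- match.arg(action)
  stopifnot(threshold > 0, threshold < 1)
  n <- nrow(cohort)
  nmiss <- vapply(cohort, function(x) sum(is.na(x)), integer(1))
  frac <- if (n > 0) nmiss / n else rep(0, length(nmiss))
  handled <- nmiss > 0 & frac < threshold
  report <- data.frame(variable = names(cohort), n_missing = nmiss,
                       frac_missing = frac, handled = handled,
                       row.names = NULL, stringsAsFactors = FALSE)
  vars <- names(cohort)[handled]
  if (length(vars)) {
    if (action == "rows") {
      keep <- !Reduce(`|`, lapply(vars, function(v) is.na(cohort[[v]])))
      cohort <- cohort[keep, , drop = FALSE]
      rownames(cohort) <- NULL
    } else {
      cohort <- cohort[, setdiff(names(cohort), vars), drop = FALSE]
    }
  }
  list(cohort = cohort, report = report)
}

#' Chained round-robin ridge imputation of numeric covariates
#'
#' Single imputation in the iterative-chained-equations style: each
#' incomplete numeric column is regressed on all other numeric covariates
#' with a ridge-regularized linear model, missing cells are replaced by the
#' regression predictions, and the procedure cycles through the incomplete
#' columns until the largest absolute cell change falls below `tol` or
#' `max_iter` rounds have run. Observed cells are never altered, and the
#' result is deterministic given the input (initialisation is by column
#' means, so no randomness is consumed; `seed` is accepted for interface
#' stability and future stochastic variants).
#'
#' @param cohort Analysis table; missingness must be confined to numeric
#'   columns.
#' @param columns Columns eligible as predictors/targets; defaults to all
#'   numeric columns.
#' @param max_iter Maximum round-robin cycles (default 10).
#' @param tol Convergence tolerance on the maximum absolute cell change
#'   (default 1e-3).
#' @param lambda Ridge penalty applied on the standardized scale
#'   (default 1e-3).
#' @param seed Unused placeholder for RNG control.
#' @return The completed table.
#' @export
impute_covariates <- function(cohort, columns = NULL, max_iter = 10L,
                              tol = 1e-3, lambda = 1e-3, seed = NULL) {
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  if (is.null(columns)) columns <- num_cols
  columns <- intersect(columns, num_cols)
  non_num_na <- setdiff(names(cohort)[vapply(cohort, anyNA, logical(1))], num_cols)
  if (length(non_num_na))
    stop("missing values in non-numeric column(s): ",
         paste(non_num_na, collapse = ", "))
  target <- columns[vapply(cohort[columns], anyNA, logical(1))]
  if (!length(target)) return(cohort)
  all_na <- target[vapply(cohort[target], function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) stop("column(s) entirely missing: ", paste(all_na, collapse = ", "))
  if (length(columns) < 2L) stop("need at least 2 numeric columns to impute")

  X <- as.matrix(cohort[columns])
  miss <- is.na(X)
  # drop constant predictors (no information, break standardisation)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  usable <- colnames(X)[is.finite(sds) & sds > 0]
  for (j in target) X[miss[, j], j] <- mean(X[, j], na.rm = TRUE)

  ridge_fit <- function(Z, y) {
    mu <- colMeans(Z); sg <- apply(Z, 2, stats::sd)
    sg[sg == 0] <- 1
    Zs <- sweep(sweep(Z, 2, mu), 2, sg, "/")
    ym <- mean(y)
    b <- solve(crossprod(Zs) + lambda * diag(ncol(Zs)), crossprod(Zs, y - ym))
    list(predict = function(Znew) {
      Zn <- sweep(sweep(Znew, 2, mu), 2, sg, "/")
      ym + drop(Zn %*% b)
    })
  }
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in target) {
      preds <- setdiff(usable, j)
      if (!length(preds)) stop("no usable predictors for column ", j)
      obs <- !miss[, j]
      fit <- ridge_fit(X[obs, preds, drop = FALSE], X[obs, j])
      new_vals <- fit$predict(X[miss[, j], preds, drop = FALSE])
      delta <- max(delta, max(abs(new_vals - X[miss[, j], j])))
      X[miss[, j], j] <- new_vals
    }
    if (delta < tol) break
  }
  for (j in target) cohort[[j]] <- X[, j]
  cohort
}

#' Variance inflation factors for a numeric design matrix
#'
#' For each column `j`, `VIF_j = 1 / (1 - R²_j)` where `R²_j` comes from the
#' least-squares regression of column `j` on all the others. Perfectly
#' collinear columns are reported with infinite VIF and flagged rather than
#' raising an error. The conventional multicollinearity screen flags
#' `VIF > 2`.
#'
#' @param x Numeric matrix or data frame of covariates (no missing values,
#'   at least two columns).
#' @param flag_threshold VIF above which a variable is flagged (default 2).
#' @return Data frame `variable`, `vif`, `flagged`.
#' @export
vif_screen <- function(x, flag_threshold = 2) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("vif_screen requires a complete (no-NA) matrix")
  if (ncol(X) < 2L) stop("need at least two columns")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(r^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vifs,
             flagged = vifs > flag_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
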