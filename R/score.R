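#' Select the representative value of one item within its scoring window
#'
#' Records outside the item's scoring window (hours from ICU admission, both
#' endpoints included) are discarded. For `first_in_window` the
#' chronologically earliest remaining value is returned, ties broken by input
#' order; for `mean_in_window` (numeric items only) the arithmetic mean of
#' the remaining values is returned. If no record falls inside the window the
#' item is missing and `NA` is returned.
#'
#' @param times Numeric vector of record times in hours from ICU admission.
#' @param values Vector of record values (numeric, or character for
#'   categorical items).
#' @param spec One registry row (a one-row data frame).
#' @return A single value, or `NA` when no record lies in the window.
#' @export
select_item_value <- function(times, values, spec) {
  stopifnot(length(times) == length(values))
  keep <- !is.na(times) & times >= spec$window_low_h & times <= spec$window_high_h
  times <- times[keep]; values <- values[keep]
  if (!length(values)) return(NA)
  if (spec$aggregation == "mean_in_window") {
    if (spec$kind == "categorical_lab")
      stop("item '", spec$name, "': mean_in_window is undefined for categorical items")
    return(mean(as.numeric(values)))
  }
  values[order(times)[1L]]
}

#' Dichotomize one item value against its reference definition
#'
#' Numeric values score 0 when inside the closed reference interval
#' (a value equal to a limit is normal; a missing bound is unbounded on that
#' side) and 1 otherwise. Categorical values score 1 when the reported
#' category is in the item's abnormal set.
#'
#' @param value A single item value.
#' @param spec One registry row.
#' @return Integer 0 (normal) or 1 (deficit).
#' @export
dichotomize <- function(value, spec) {
  if (spec$kind == "categorical_lab")
    return(as.integer(as.character(value) %in% abnormal_set(spec)))
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v))
    stop("non-numeric value '", value, "' for numeric item '", spec$name, "'")
  lo_ok <- is.na(spec$reference_low) || v >= spec$reference_low
  hi_ok <- is.na(spec$reference_high) || v <= spec$reference_high
  as.integer(!(lo_ok && hi_ok))
}

#' Compute the laboratory frailty index per ICU stay
#'
#' For every stay and registry item, the in-window value is selected
#' ([select_item_value()]) and dichotomized against the reference definition
#' ([dichotomize()]). The FI-Lab score is the number of deficits divided by
#' the denominator: by default the number of measured items (standard
#' deficit-accumulation practice when some items are unmeasured), optionally
#' the fixed registry length. Stays missing more than `max_missing` items
#' (default 12) are flagged ineligible and get no score.
#'
#' @param lab_events Long data frame with columns `stay_id`, `item`,
#'   `charttime_h` (hours from ICU admission) and `value`.
#' @param vitals Long data frame with the same columns (numeric values);
#'   may be `NULL` if vital-sign items are absent from the registry or
#'   included in `lab_events`.
#' @param registry A `filab_registry`; defaults to the shipped 33-item one.
#' @param stay_ids Optional vector of stay ids to score (so stays with no
#'   records at all still appear, as all-missing). Defaults to ids seen in
#'   the input records.
#' @param max_missing Maximum number of unmeasured items tolerated before a
#'   stay is ineligible (default 12).
#' @param denominator `"measured"` (default) or `"fixed"` (registry length).
#' @return Data frame with one row per stay: `stay_id`, `n_items_total`,
#'   `n_measured`, `n_missing`, `n_deficits`, `score` (`NA` when
#'   ineligible), `eligible`.
#' @examples
#' reg <- default_registry()[1:3, ]
#' labs <- data.frame(stay_id = 1, item = reg$name, charttime_h = 1,
#'                    value = c("13", "5", "200"))
#' compute_filab(labs, registry = validate_registry(reg))
#' @export
compute_filab <- function(lab_events, vitals = NULL, registry = default_registry(),
                          stay_ids = NULL, max_missing = 12L,
                          denominator = c("measured", "fixed")) {
  denominator <- match.arg(denominator)
  registry <- validate_registry(as.data.frame(registry))
  rec <- rbind_records(lab_events, vitals)
  if (is.null(stay_ids)) stay_ids <- unique(rec$stay_id)
  stay_ids <- unique(stay_ids)
  rec <- rec[rec$item %in% registry$name & rec$stay_id %in% stay_ids, , drop = FALSE]

  # per (stay, item) value selection, vectorized over the whole record table
  reg_idx <- match(rec$item, registry$name)
  lo <- registry$window_low_h[reg_idx]; hi <- registry$window_high_h[reg_idx]
  in_win <- !is.na(rec$charttime_h) & rec$charttime_h >= lo & rec$charttime_h <= hi
  rec <- rec[in_win, , drop = FALSE]
  reg_idx <- reg_idx[in_win]

  deficits <- integer(0); d_stay <- character(0); d_item <- character(0)
  if (nrow(rec)) {
    agg <- registry$aggregation[reg_idx]
    key <- paste(rec$stay_id, rec$item, sep = "\r")
    # first_in_window: stable order by time then input order
    ord <- order(key, rec$charttime_h, seq_len(nrow(rec)))
    first <- ord[!duplicated(key[ord])]
    is_mean <- agg == "mean_in_window"
    sel_key <- key[first]
    sel_val <- rec$value[first]
    if (any(is_mean)) {
      mkey <- key[is_mean]
      mval <- suppressWarnings(as.numeric(rec$value[is_mean]))
      means <- tapply(mval, mkey, mean)
      repl <- match(sel_key, names(means))
      sel_val[!is.na(repl)] <- as.character(means[repl[!is.na(repl)]])
    }
    sel_stay <- rec$stay_id[first]
    sel_item <- rec$item[first]
    def <- integer(length(sel_val))
    for (k in seq_len(nrow(registry))) {
      pick <- which(sel_item == registry$name[k])
      if (!length(pick)) next
      spec <- registry[k, ]
      if (spec$kind == "categorical_lab") {
        def[pick] <- as.integer(sel_val[pick] %in% abnormal_set(spec))
      } else {
        v <- suppressWarnings(as.numeric(sel_val[pick]))
        if (anyNA(v)) {
          bad <- pick[is.na(v)][1L]
          stop("non-numeric value '", sel_val[bad], "' for numeric item '",
               spec$name, "' in stay ", sel_stay[bad])
        }
        lo_ok <- if (is.na(spec$reference_low)) TRUE else v >= spec$reference_low
        hi_ok <- if (is.na(spec$reference_high)) TRUE else v <= spec$reference_high
        def[pick] <- as.integer(!(lo_ok & hi_ok))
      }
    }
    deficits <- def; d_stay <- as.character(sel_stay); d_item <- sel_item
  }

  n_total <- nrow(registry)
  sid <- as.character(stay_ids)
  n_measured <- as.integer(table(factor(d_stay, levels = sid)))
  n_def <- as.integer(tapply(deficits, factor(d_stay, levels = sid), sum))
  n_def[is.na(n_def)] <- 0L
  n_missing <- n_total - n_measured
  eligible <- n_missing <= max_missing
  denom <- if (denominator == "measured") n_measured else rep(n_total, length(sid))
  score <- ifelse(eligible & denom > 0, n_def / denom, NA_real_)
  out <- data.frame(stay_id = stay_ids, n_items_total = n_total,
                    n_measured = n_measured, n_missing = n_missing,
                    n_deficits = n_def, score = score, eligible = eligible,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

rbind_records <- function(lab_events, vitals) {
  cols <- c("stay_id", "item", "charttime_h", "value")
  norm <- function(x) {
    if (is.null(x) || nrow(x) == 0L)
      return(data.frame(stay_id = character(0), item = character(0),
                        charttime_h = numeric(0), value = character(0),
                        stringsAsFactors = FALSE))
    miss <- setdiff(cols, names(x))
    if (length(miss)) stop("record table missing columns: ", paste(miss, collapse = ", "))
    data.frame(stay_id = x$stay_id, item = as.character(x$item),
               charttime_h = as.numeric(x$charttime_h),
               value = as.character(x$value), stringsAsFactors = FALSE)
  }
  rbind(norm(lab_events), norm(vitals))
}

#' Assign FI-Lab tertile labels
#'
#' Labels are `T1` for scores below the first cutpoint, `T2` for scores in
#' the half-open interval `[c1, c2)` and `T3` for scores at or above the
#' second cutpoint — the printed-cohort convention (e.g. T3 is
#' "score >= 0.54"). Cutpoints may be fixed values or the cohort-empirical
#' 33rd/67th percentiles.
#'
#' @param score Numeric vector of FI-Lab scores in `[0, 1]`.
#' @param cutpoints Strictly increasing pair of cutpoints, or `"empirical"`
#'   to use the score vector's own tertile boundaries.
#' @return Factor with levels `T1`, `T2`, `T3` (`NA` for `NA` scores).
#' @examples
#' assign_tertile(c(0.42, 0.43, 0.54), cutpoints = c(0.43, 0.54))
#' @export
assign_tertile <- function(score, cutpoints = "empirical") {
  if (identical(cutpoints, "empirical"))
    cutpoints <- unname(stats::quantile(score, c(1, 2) / 3, na.rm = TRUE, type = 7))
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != 2L || !all(is.finite(cutpoints)) ||
      cutpoints[1] >= cutpoints[2])
    stop("cutpoints must be two strictly increasing finite values")
  lab <- ifelse(score < cutpoints[1], "T1",
                ifelse(score < cutpoints[2], "T2", "T3"))
  factor(lab, levels = c("T1", "T2", "T3"))
}
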