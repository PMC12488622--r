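#' Item registry for the laboratory frailty index
#'
#' The FI-Lab is built from a registry of scoreable items. Each item is either
#' a numeric laboratory test with a clinical reference interval, a categorical
#' (urinalysis-style) test with a set of abnormal result categories, or a
#' vital sign averaged over the first day of the ICU stay. The shipped default
#' registry has 33 items: 20 blood tests, 4 arterial blood gas values,
#' 6 urinalysis values and 3 vital signs. Reference intervals in the default
#' registry are standard adult clinical intervals and are fully
#' user-overridable: scoring always runs against whatever registry is passed.
#'
#' A registry is a `data.frame` with class `filab_registry` and columns
#' `name`, `kind` (`numeric_lab`, `categorical_lab`, `vital_sign`),
#' `reference_low`, `reference_high`, `abnormal_categories`
#' (semicolon-separated), `window_low_h`, `window_high_h` (hours from ICU
#' admission, both endpoints included) and `aggregation` (`first_in_window`
#' or `mean_in_window`).
#'
#' @param path Path to a registry CSV with the columns listed above.
#' @return A validated `filab_registry` data frame.
#' @examples
#' reg <- default_registry()
#' nrow(reg)  # 33
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("abnormal_categories" %in% names(raw))
    raw$abnormal_categories <- as.character(raw$abnormal_categories)
  if (nrow(raw) == 0L) stop("registry file is empty: ", path)
  validate_registry(raw)
}

#' @rdname load_registry
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "filab_registry_default.csv",
                            package = "filabicu", mustWork = TRUE))
}

valid_kinds <- c("numeric_lab", "categorical_lab", "vital_sign")

#' Validate a registry data frame
#'
#' Checks the per-item invariants: unique names; numeric items carry at least
#' one reference bound with `reference_low < reference_high` when both are
#' present; categorical items carry a non-empty abnormal-category set;
#' windows are proper intervals; `mean_in_window` is not allowed for
#' categorical items.
#'
#' @param reg A data frame with registry columns.
#' @return The same data frame, classed `filab_registry`.
#' @export
validate_registry <- function(reg) {
  needed <- c("name", "kind", "reference_low", "reference_high",
              "abnormal_categories", "window_low_h", "window_high_h",
              "aggregation")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols))
    stop("registry missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop("duplicate item name in registry: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  bad_kind <- setdiff(unique(reg$kind), valid_kinds)
  if (length(bad_kind))
    stop("unknown item kind: ", paste(bad_kind, collapse = ", "))
  reg$reference_low <- as.numeric(reg$reference_low)
  reg$reference_high <- as.numeric(reg$reference_high)
  reg$abnormal_categories <- ifelse(is.na(reg$abnormal_categories), "",
                                    reg$abnormal_categories)
  for (i in seq_len(nrow(reg))) {
    it <- reg[i, ]
    numeric_kind <- it$kind %in% c("numeric_lab", "vital_sign")
    if (numeric_kind) {
      if (is.na(it$reference_low) && is.na(it$reference_high))
        stop("item '", it$name, "': numeric item needs at least one reference bound")
      if (!is.na(it$reference_low) && !is.na(it$reference_high) &&
          it$reference_low >= it$reference_high)
        stop("item '", it$name, "': reference_low must be < reference_high")
    } else {
      if (!nzchar(it$abnormal_categories))
        stop("item '", it$name, "': categorical item needs abnormal_categories")
      if (identical(it$aggregation, "mean_in_window"))
        stop("item '", it$name, "': mean_in_window is undefined for categorical items")
    }
    if (is.na(it$window_low_h) || is.na(it$window_high_h) ||
        it$window_low_h >= it$window_high_h)
      stop("item '", it$name, "': invalid scoring window")
    if (!it$aggregation %in% c("first_in_window", "mean_in_window"))
      stop("item '", it$name, "': unknown aggregation '", it$aggregation, "'")
  }
  class(reg) <- c("filab_registry", "data.frame")
  reg
}

# abnormal category set for one item, as a character vector
abnormal_set <- function(spec) {
  out <- strsplit(spec$abnormal_categories, ";", fixed = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}
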