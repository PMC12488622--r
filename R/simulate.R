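#' Configuration for the synthetic ICU cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' describe a critically ill asthma cohort at ICU admission: a central FI-Lab
#' near 0.48 (per-item abnormality probability 0.48 across the 33 default
#' items), 2% per-item missingness, a per-0.1-unit FI-Lab log hazard of
#' log(1.32), a baseline death hazard of 0.0013/day calibrated to a 28-day
#' mortality around 13.2% under that effect size, and an ICU discharge clock
#' with median stay 2.8 days. Covariates (demographics, severity scores,
#' comorbidity and intervention flags) are drawn from simple fixed
#' distributions and carry zero hazard effect unless `covariate_effects`
#' says otherwise; they are inert columns meant for adjustment, calibration
#' and discrimination experiments with known structure.
#'
#' @param n_patients Number of ICU stays to simulate.
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical tables.
#' @param registry Item registry the deficits are generated against.
#' @param abnormality_probs Named per-item deficit probabilities in `[0,1]`;
#'   a single unnamed value is recycled to all items.
#' @param missingness_probs Named per-item missingness probabilities; a
#'   single unnamed value is recycled.
#' @param beta_filab_per_0_1 True log hazard ratio per 0.1 FI-Lab units.
#' @param covariate_effects Named log-hazard effects per unit of the named
#'   stay covariate (binary flags count 0/1). Default: all zero.
#' @param baseline_hazard_rate Baseline death hazard per day (> 0).
#' @param icu_discharge_rate Rate of the independent exponential ICU
#'   discharge clock per day (> 0).
#' @param admin_censor_days Administrative censoring horizons; both 28- and
#'   90-day outcomes are always emitted.
#' @param filter_violation_fracs Named fractions of stays made to violate
#'   each inclusion rule (`age_under_18`, `los_under_24h`, `pregnancy`,
#'   `repeat_stay`, `excess_missing_items`, `missing_required`), to exercise
#'   the exclusion cascade.
#' @param window_violation_frac Fraction of lab records whose charttime is
#'   moved outside the scoring window (makes the item unscoreable).
#' @param pao2_fio2_missing_frac Fraction of stays with missing PaO2/FiO2
#'   (the covariate routed to imputation).
#' @param sparse_missing_frac Fraction of stays with missing APSIII
#'   (a below-1%-missingness covariate routed to complete-case removal).
#' @param frailty_sd Standard deviation of an optional per-stay latent
#'   factor added on the logit scale to every item's abnormality
#'   probability, inducing positive inter-item correlation. 0 (default)
#'   keeps items independent.
#' @return A validated `filab_sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L,
                       seed = 1L,
                       registry = default_registry(),
                       abnormality_probs = 0.48,
                       missingness_probs = 0.02,
                       beta_filab_per_0_1 = log(1.32),
                       covariate_effects = NULL,
                       baseline_hazard_rate = 0.0013,
                       icu_discharge_rate = log(2) / 2.8,
                       admin_censor_days = c(28, 90),
                       filter_violation_fracs = c(age_under_18 = 0.02,
                                                  los_under_24h = 0.02,
                                                  pregnancy = 0.02,
                                                  repeat_stay = 0.02,
                                                  excess_missing_items = 0.02,
                                                  missing_required = 0.02),
                       window_violation_frac = 0,
                       pao2_fio2_missing_frac = 0.05,
                       sparse_missing_frac = 0.005,
                       frailty_sd = 0) {
  registry <- validate_registry(as.data.frame(registry))
  items <- registry$name
  expand <- function(p, what) {
    if (length(p) == 1L && is.null(names(p))) p <- stats::setNames(rep(p, length(items)), items)
    if (!all(items %in% names(p)))
      stop(what, " must name every registry item")
    p <- p[items]
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop(what, " must lie in [0, 1]")
    p
  }
  abnormality_probs <- expand(abnormality_probs, "abnormality_probs")
  missingness_probs <- expand(missingness_probs, "missingness_probs")
  if (!is.finite(beta_filab_per_0_1)) stop("beta_filab_per_0_1 must be finite")
  if (!is.finite(baseline_hazard_rate) || baseline_hazard_rate <= 0)
    stop("baseline_hazard_rate must be a positive rate")
  if (!is.finite(icu_discharge_rate) || icu_discharge_rate <= 0)
    stop("icu_discharge_rate must be a positive rate")
  fv <- filter_violation_fracs
  if (any(!is.finite(fv)) || any(fv < 0) || any(fv > 1))
    stop("filter_violation_fracs must lie in [0, 1]")
  for (nm in c("window_violation_frac", "pao2_fio2_missing_frac",
               "sparse_missing_frac")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
  }
  if (!is.finite(frailty_sd) || frailty_sd < 0) stop("frailty_sd must be >= 0")
  if (n_patients < 0 || n_patients != round(n_patients))
    stop("n_patients must be a non-negative integer")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 registry = registry, abnormality_probs = abnormality_probs,
                 missingness_probs = missingness_probs,
                 beta_filab_per_0_1 = beta_filab_per_0_1,
                 covariate_effects = covariate_effects,
                 baseline_hazard_rate = baseline_hazard_rate,
                 icu_discharge_rate = icu_discharge_rate,
                 admin_censor_days = admin_censor_days,
                 filter_violation_fracs = fv,
                 window_violation_frac = window_violation_frac,
                 pao2_fio2_missing_frac = pao2_fio2_missing_frac,
                 sparse_missing_frac = sparse_missing_frac,
                 frailty_sd = frailty_sd),
            class = "filab_sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' Scalar fields use the [sim_config()] argument names; per-item probability
#' maps are given as named mappings.
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `filab_sim_config`.
#' @export
sim_config_from_yaml <- function(path, ...) {
  conf <- yaml::read_yaml(path)
  for (nm in c("abnormality_probs", "missingness_probs",
               "covariate_effects", "filter_violation_fracs"))
    if (!is.null(conf[[nm]])) conf[[nm]] <- unlist(conf[[nm]])
  over <- list(...)
  conf[names(over)] <- over
  do.call(sim_config, conf)
}

#' Generate a synthetic ICU cohort with known FI-Lab and hazard structure
#'
#' Simulates a MIMIC-like extract: a stays table (demographics, severity
#' scores, comorbidity and intervention flags, outcomes), long lab-event and
#' vital-sign tables, and a truth table holding each stay's generated deficit
#' count and FI-Lab score. Deficits are per-item Bernoulli draws; numeric
#' values are placed uniformly inside the reference interval when normal and
#' on an interval extending 10--50% of the reference width beyond a randomly
#' chosen boundary when abnormal (one-sided items always cross their single
#' bound); categorical deficits sample an abnormal category. Missing items
#' produce no record. Death times are exponential with log hazard
#' `beta_filab_per_0_1 * (score / 0.1)` plus any covariate effects; 28- and
#' 90-day outcomes are administratively censored at their horizons, and ICU
#' death means death before an independent exponential discharge time.
#' Configured fractions of stays violate each inclusion rule so the
#' downstream exclusion cascade has work to do.
#'
#' @param config A `filab_sim_config` from [sim_config()].
#' @return A `filab_raw_tables` list with elements `stays`, `lab_events`,
#'   `vitals`, `truth`.
#' @examples
#' tabs <- generate_cohort(sim_config(n_patients = 50, seed = 1))
#' head(tabs$truth)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "filab_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  reg <- config$registry
  n_items <- nrow(reg)
  stay_id <- if (n > 0) sprintf("S%06d", seq_len(n)) else character(0)

  # --- item-level deficit / missingness structure ---------------------------
  p_abn <- matrix(rep(config$abnormality_probs, each = n), nrow = n,
                  ncol = n_items)
  if (config$frailty_sd > 0 && n > 0) {
    u <- stats::rnorm(n, 0, config$frailty_sd)
    p_abn <- stats::plogis(stats::qlogis(pmin(pmax(p_abn, 1e-12), 1 - 1e-12)) + u)
  }
  deficit <- matrix(stats::rbinom(n * n_items, 1L, as.vector(p_abn)),
                    nrow = n, ncol = n_items)
  missing <- matrix(stats::rbinom(n * n_items, 1L,
                                  rep(config$missingness_probs, each = n)),
                    nrow = n, ncol = n_items)
  colnames(deficit) <- colnames(missing) <- reg$name

  # inclusion-rule violations
  pick <- function(frac) if (n > 0) which(stats::runif(n) < frac) else integer(0)
  fv <- config$filter_violation_fracs
  viol_age <- pick(fv[["age_under_18"]])
  viol_los <- pick(fv[["los_under_24h"]])
  viol_preg <- pick(fv[["pregnancy"]])
  viol_rep <- pick(fv[["repeat_stay"]])
  viol_mis <- pick(fv[["excess_missing_items"]])
  viol_req <- pick(fv[["missing_required"]])
  if (length(viol_mis)) {
    need <- 13L  # enough missing items to break FI-Lab eligibility
    for (i in viol_mis) {
      drop <- sample.int(n_items, min(need + sample.int(5L, 1L) - 1L, n_items))
      missing[i, drop] <- 1L
    }
  }
  measured <- missing == 0L
  n_measured <- rowSums(measured)
  n_def <- rowSums(deficit * measured)
  true_score <- ifelse(n_measured > 0, n_def / n_measured, NA_real_)

  # --- covariates (inert unless covariate_effects says otherwise) -----------
  st <- data.frame(stay_id = stay_id, stringsAsFactors = FALSE)
  if (n > 0) {
    st$admission_time <- format(as.POSIXct("2140-01-01 00:00:00", tz = "UTC") +
                                  stats::runif(n, 0, 365 * 10) * 86400,
                                "%Y-%m-%d %H:%M:%S")
    st$age <- pmax(18, stats::rnorm(n, 61.3, 17.1))
    st$sex <- ifelse(stats::rbinom(n, 1, 0.432) == 1, "male", "female")
    st$race <- ifelse(stats::rbinom(n, 1, 0.588) == 1, "white", "nonwhite")
    st$smoking <- stats::rbinom(n, 1, 0.084)
    st$obesity <- stats::rbinom(n, 1, 0.222)
    st$respiratory_rate <- stats::rnorm(n, 29.3, 6.9)
    st$bicarbonate <- stats::rnorm(n, 24.1, 4.6)
    st$pao2_fio2 <- exp(stats::rnorm(n, log(175), 0.55))
    st$apsiii <- pmax(0, stats::rnorm(n, 47.4, 21.9))
    st$sofa <- pmin(24L, stats::rpois(n, 5))
    st$apache_ii <- pmax(0, stats::rnorm(n, 18.4, 7.7))
    st$cci <- pmin(20L, stats::rpois(n, 5))
    st$heart_failure <- stats::rbinom(n, 1, 0.280)
    st$hypertension <- stats::rbinom(n, 1, 0.629)
    st$diabetes <- stats::rbinom(n, 1, 0.290)
    st$copd <- stats::rbinom(n, 1, 0.061)
    st$aeba <- stats::rbinom(n, 1, 0.048)
    st$cardiac_shock <- stats::rbinom(n, 1, 0.059)
    st$sepsis <- stats::rbinom(n, 1, 0.600)
    st$mv <- stats::rbinom(n, 1, 0.515)
    st$vasopressor <- stats::rbinom(n, 1, 0.385)
    st$glucocorticoid <- stats::rbinom(n, 1, 0.198)
    st$montelukast <- stats::rbinom(n, 1, 0.063)
    st$is_first_icu_stay <- 1L
    st$pregnant <- 0L
    st$age[viol_age] <- stats::runif(length(viol_age), 14, 17.9)
    st$pregnant[viol_preg] <- 1L
    st$is_first_icu_stay[viol_rep] <- 0L
    if (length(viol_req)) {
      req_cols <- c("respiratory_rate", "bicarbonate", "glucocorticoid", "montelukast")
      for (i in viol_req) st[i, sample(req_cols, 1L)] <- NA
    }
    st$pao2_fio2[pick(config$pao2_fio2_missing_frac)] <- NA_real_
    st$apsiii[pick(config$sparse_missing_frac)] <- NA_real_
  } else {
    for (col in c("admission_time", "sex", "race")) st[[col]] <- character(0)
    for (col in c("age", "respiratory_rate", "bicarbonate", "pao2_fio2",
                  "apsiii", "sofa", "apache_ii", "cci")) st[[col]] <- numeric(0)
    for (col in c("smoking", "obesity", "heart_failure", "hypertension",
                  "diabetes", "copd", "aeba", "cardiac_shock", "sepsis", "mv",
                  "vasopressor", "glucocorticoid", "montelukast",
                  "is_first_icu_stay", "pregnant")) st[[col]] <- integer(0)
  }

  # --- survival under the exponential proportional-hazards model ------------
  lp <- config$beta_filab_per_0_1 * (ifelse(is.na(true_score), 0, true_score) / 0.1)
  if (!is.null(config$covariate_effects) && n > 0) {
    for (nm in names(config$covariate_effects)) {
      x <- st[[nm]]
      if (is.null(x)) stop("covariate_effects names unknown covariate '", nm, "'")
      if (is.character(x)) x <- as.integer(x %in% c("male", "white"))
      x[is.na(x)] <- 0
      lp <- lp + config$covariate_effects[[nm]] * x
    }
  }
  t_death <- if (n > 0) stats::rexp(n, config$baseline_hazard_rate * exp(lp)) else numeric(0)
  t_disch <- if (n > 0) stats::rexp(n, config$icu_discharge_rate) else numeric(0)
  st$time_28d <- pmin(t_death, 28); st$death_28d <- as.integer(t_death <= 28)
  st$time_90d <- pmin(t_death, 90); st$death_90d <- as.integer(t_death <= 90)
  st$time_icu <- pmin(t_death, t_disch)
  st$death_icu <- as.integer(t_death <= t_disch)
  st$icu_los <- pmax(st$time_icu, 1.05)  # stays below 24 h only via injected violations
  st$icu_los[viol_los] <- stats::runif(length(viol_los), 0.1, 0.95)

  # --- long lab / vital records --------------------------------------------
  is_vital <- reg$kind == "vital_sign"
  emit <- which(measured, arr.ind = TRUE)
  lab_events <- vitals <- data.frame(stay_id = character(0), item = character(0),
                                     charttime_h = numeric(0), value = character(0),
                                     stringsAsFactors = FALSE)
  if (nrow(emit)) {
    emit <- emit[order(emit[, 1], emit[, 2]), , drop = FALSE]
    ii <- emit[, 2]
    si <- emit[, 1]
    dflag <- deficit[emit]
    val <- character(nrow(emit))
    num_kind <- reg$kind[ii] %in% c("numeric_lab", "vital_sign")
    if (any(num_kind)) {
      k <- which(num_kind)
      lo <- reg$reference_low[ii[k]]; hi <- reg$reference_high[ii[k]]
      width <- ifelse(is.na(lo) | is.na(hi), pmax(abs(ifelse(is.na(hi), lo, hi)), 1),
                      hi - lo)
      inside_lo <- ifelse(is.na(lo), hi - width, lo)
      inside_hi <- ifelse(is.na(hi), lo + width, hi)
      u <- stats::runif(length(k))
      v_norm <- inside_lo + u * (inside_hi - inside_lo)
      # deficit values: 10-50% of the reference width beyond a random bound
      side_hi <- ifelse(is.na(hi), FALSE, ifelse(is.na(lo), TRUE,
                                                 stats::runif(length(k)) < 0.5))
      ext <- width * stats::runif(length(k), 0.1, 0.5)
      v_abn <- ifelse(side_hi, hi + ext, lo - ext)
      v <- ifelse(dflag[k] == 1L, v_abn, v_norm)
      val[k] <- sprintf("%.10g", v)
    }
    if (any(!num_kind)) {
      val[!num_kind] <- "negative"
      for (k in which(reg$kind == "categorical_lab")) {
        rows <- which(ii == k & dflag == 1L)
        if (length(rows)) {
          cats <- abnormal_set(reg[k, ])
          val[rows] <- cats[sample.int(length(cats), length(rows), replace = TRUE)]
        }
      }
    }
    ct <- numeric(nrow(emit))
    ct[is_vital[ii]] <- stats::runif(sum(is_vital[ii]), 0, 24)
    ct[!is_vital[ii]] <- stats::runif(sum(!is_vital[ii]), -6, 24)
    if (config$window_violation_frac > 0) {
      lab_rows <- which(!is_vital[ii])
      move <- lab_rows[stats::runif(length(lab_rows)) < config$window_violation_frac]
      ct[move] <- stats::runif(length(move), -12, -6.001)
    }
    recs <- data.frame(stay_id = stay_id[si], item = reg$name[ii],
                       charttime_h = ct, value = val, stringsAsFactors = FALSE)
    lab_events <- recs[!is_vital[ii], , drop = FALSE]
    vitals <- recs[is_vital[ii], , drop = FALSE]
    rownames(lab_events) <- rownames(vitals) <- NULL
  }

  truth <- data.frame(stay_id = stay_id, n_measured = n_measured,
                      n_deficits = n_def, true_score = true_score,
                      stringsAsFactors = FALSE)
  structure(list(stays = st, lab_events = lab_events, vitals = vitals,
                 truth = truth),
            class = "filab_raw_tables")
}

#' Write or read the simulator's tables as CSV files
#'
#' `write_tables()` emits `stays.csv`, `labevents.csv`, `vitals.csv` and
#' `truth.csv` in `directory`; `read_tables()` reads them back into a
#' `filab_raw_tables` object. Missing values are empty cells; times are
#' signed hours from ICU admission.
#'
#' @param tables A `filab_raw_tables` object.
#' @param directory Output/input directory (created if absent).
#' @return `write_tables()` returns the file paths invisibly;
#'   `read_tables()` returns a `filab_raw_tables`.
#' @export
write_tables <- function(tables, directory) {
  stopifnot(inherits(tables, "filab_raw_tables"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- c(stays = "stays.csv", lab_events = "labevents.csv",
             vitals = "vitals.csv", truth = "truth.csv")
  paths <- file.path(directory, files)
  names(paths) <- names(files)
  for (nm in names(files))
    utils::write.csv(tables[[nm]], paths[[nm]], row.names = FALSE, na = "")
  invisible(paths)
}

#' @rdname write_tables
#' @export
read_tables <- function(directory) {
  rd <- function(f, chr_cols = character(0)) {
    x <- utils::read.csv(file.path(directory, f), stringsAsFactors = FALSE,
                         na.strings = "")
    for (cc in intersect(chr_cols, names(x))) x[[cc]] <- as.character(x[[cc]])
    x
  }
  structure(list(stays = rd("stays.csv", c("stay_id", "sex", "race")),
                 lab_events = rd("labevents.csv", c("stay_id", "item", "value")),
                 vitals = rd("vitals.csv", c("stay_id", "item", "value")),
                 truth = rd("truth.csv", "stay_id")),
            class = "filab_raw_tables")
}
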