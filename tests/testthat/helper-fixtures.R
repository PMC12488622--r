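# Shared fixtures: tiny registries, record builders, and a bare-bones
# exponential survival simulator used as an independent oracle for the
# model-fitting tests (it bypasses the package's cohort generator).

mini_registry <- function() {
  validate_registry(data.frame(
    name = c("sodium", "glucose", "lactate", "urine_protein", "sbp"),
    kind = c("numeric_lab", "numeric_lab", "numeric_lab", "categorical_lab",
             "vital_sign"),
    reference_low = c(135, 70, 0.5, NA, 90),
    reference_high = c(145, 110, 2.0, NA, 140),
    abnormal_categories = c("", "", "", "trace;1+;2+;3+;positive", ""),
    window_low_h = c(-6, -6, -6, -6, 0),
    window_high_h = c(24, 24, 24, 24, 24),
    aggregation = c("first_in_window", "first_in_window", "first_in_window",
                    "first_in_window", "mean_in_window"),
    stringsAsFactors = FALSE))
}

records <- function(stay_id, item, charttime_h, value) {
  data.frame(stay_id = stay_id, item = item, charttime_h = charttime_h,
             value = as.character(value), stringsAsFactors = FALSE)
}

# stay records covering every default-registry item once, all abnormal (or
# all normal), at in-window times
full_stay_records <- function(registry = default_registry(), abnormal = TRUE,
                              stay_id = "S1") {
  val <- character(nrow(registry))
  tt <- numeric(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    it <- registry[i, ]
    tt[i] <- if (it$kind == "vital_sign") 2 else 1
    if (it$kind == "categorical_lab") {
      val[i] <- if (abnormal) strsplit(it$abnormal_categories, ";")[[1]][1] else "negative"
    } else if (abnormal) {
      val[i] <- as.character(if (!is.na(it$reference_high))
        it$reference_high + 1 else it$reference_low - 1)
    } else {
      val[i] <- as.character(if (!is.na(it$reference_low) && !is.na(it$reference_high))
        (it$reference_low + it$reference_high) / 2
        else if (is.na(it$reference_low)) it$reference_high - 0.001
        else it$reference_low + 1)
    }
  }
  records(stay_id, registry$name, tt, val)
}

# independent exponential proportional-hazards simulator: score drawn as a
# truncated normal, death time exponential with log-hazard beta * score/0.1,
# administrative censoring at `horizon` days
sim_surv_cohort <- function(n, beta_per01, horizon = 28, base_rate = 0.0013,
                            score_mean = 0.48, score_sd = 0.087,
                            extra = NULL) {
  s <- pmin(pmax(stats::rnorm(n, score_mean, score_sd), 0), 1)
  lp <- beta_per01 * s / 0.1
  if (!is.null(extra)) lp <- lp + extra$beta * extra$x
  t_death <- stats::rexp(n, base_rate * exp(lp))
  data.frame(filab_score = s,
             time_28d = pmin(t_death, horizon),
             death_28d = as.integer(t_death <= horizon),
             time_90d = pmin(t_death, 90),
             death_90d = as.integer(t_death <= 90))
}

# a stays table row with no rule violations and complete required fields
clean_stay <- function(stay_id, ...) {
  base <- data.frame(stay_id = stay_id, age = 60, icu_los = 3, pregnant = 0L,
                     is_first_icu_stay = 1L, respiratory_rate = 28,
                     bicarbonate = 24, glucocorticoid = 0L, montelukast = 0L,
                     stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# brute-force AUC by exhaustive pair counting (wins + half ties)
auc_bruteforce <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force two-group log-rank chi-square: hypergeometric O-E over the
# pooled distinct event times
logrank_bruteforce <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2L)
  times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g == 1L)
    e1 <- d * n1 / n
    U <- U + (d1 - e1)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (U^2) / V
}
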