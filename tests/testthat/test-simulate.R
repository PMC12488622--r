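test_that("configuration validation names the offending field", {
  expect_error(sim_config(abnormality_probs = 1.2), "abnormality_probs")
  expect_error(sim_config(missingness_probs = -0.1), "missingness_probs")
  expect_error(sim_config(baseline_hazard_rate = 0), "baseline_hazard_rate")
  expect_error(sim_config(icu_discharge_rate = -1), "icu_discharge_rate")
  expect_error(sim_config(beta_filab_per_0_1 = NaN), "beta_filab_per_0_1")
  expect_error(sim_config(n_patients = -5), "n_patients")
  expect_error(sim_config(window_violation_frac = 2), "window_violation_frac")
})

test_that("identical configurations give bit-identical tables", {
  cfg <- sim_config(n_patients = 150, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(sim_config(n_patients = 150, seed = 7))
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_patients = 150, seed = 8))
  expect_false(identical(a$truth, c2$truth))
})

test_that("degenerate generating probabilities behave as specified", {
  zero <- generate_cohort(sim_config(n_patients = 80, seed = 3,
                                     abnormality_probs = 0,
                                     missingness_probs = 0))
  expect_true(all(zero$truth$true_score == 0))
  all1 <- generate_cohort(sim_config(n_patients = 40, seed = 3,
                                     abnormality_probs = 1,
                                     missingness_probs = 0,
                                     filter_violation_fracs = c(
                                       age_under_18 = 0, los_under_24h = 0,
                                       pregnancy = 0, repeat_stay = 0,
                                       excess_missing_items = 0,
                                       missing_required = 0)))
  expect_true(all(all1$truth$true_score == 1))
})

test_that("mean truth score converges to the item abnormality probability", {
  cfg <- sim_config(n_patients = 50000, seed = 5, abnormality_probs = 0.5,
                    missingness_probs = 0,
                    filter_violation_fracs = c(age_under_18 = 0,
                                               los_under_24h = 0, pregnancy = 0,
                                               repeat_stay = 0,
                                               excess_missing_items = 0,
                                               missing_required = 0))
  tabs <- generate_cohort(cfg)
  expect_lt(abs(mean(tabs$truth$true_score) - 0.5), 0.005)
})

test_that("per-item abnormality and missingness match their configured rates", {
  reg <- default_registry()
  p_abn <- setNames(seq(0.1, 0.9, length.out = 33), reg$name)
  p_mis <- setNames(rep(c(0.05, 0.15), length.out = 33), reg$name)
  n <- 4000
  cfg <- sim_config(n_patients = n, seed = 21, abnormality_probs = p_abn,
                    missingness_probs = p_mis,
                    filter_violation_fracs = c(age_under_18 = 0,
                                               los_under_24h = 0, pregnancy = 0,
                                               repeat_stay = 0,
                                               excess_missing_items = 0,
                                               missing_required = 0))
  tabs <- generate_cohort(cfg)
  rec <- rbind(tabs$lab_events, tabs$vitals)
  counts <- table(factor(rec$item, levels = reg$name))
  miss_emp <- 1 - as.numeric(counts) / n
  se_mis <- sqrt(p_mis * (1 - p_mis) / n)
  expect_true(all(abs(miss_emp - p_mis) <= 3 * se_mis + 1e-9))

  # abnormality among emitted records, via the scoring path itself
  for (it in c("sodium", "lactate", "urine_protein", "heart_rate")) {
    spec <- reg[reg$name == it, ]
    v <- rec$value[rec$item == it]
    def <- vapply(v, function(x) dichotomize(x, spec), integer(1))
    p <- p_abn[[it]]
    expect_lt(abs(mean(def) - p), 3 * sqrt(p * (1 - p) / length(def)) + 1e-9)
  }
})

test_that("a binary covariate effect reproduces its hazard ratio in event rates", {
  cfg <- sim_config(n_patients = 12000, seed = 9, beta_filab_per_0_1 = 0,
                    covariate_effects = c(sepsis = log(2)))
  tabs <- generate_cohort(cfg)
  st <- tabs$stays
  # exponential rate MLE = events / person-time, per covariate group
  rate <- function(d) sum(d$death_90d) / sum(d$time_90d)
  d1 <- sum(st$death_90d[st$sepsis == 1]); d0 <- sum(st$death_90d[st$sepsis == 0])
  ratio <- rate(st[st$sepsis == 1, ]) / rate(st[st$sepsis == 0, ])
  expect_lt(abs(log(ratio) - log(2)), 3 * sqrt(1 / d1 + 1 / d0))
})

test_that("scoring the emitted records reproduces the truth table exactly", {
  cfg <- sim_config(n_patients = 800, seed = 13, window_violation_frac = 0)
  tabs <- generate_cohort(cfg)
  sc <- compute_filab(tabs$lab_events, tabs$vitals, cfg$registry,
                      stay_ids = tabs$stays$stay_id)
  tr <- tabs$truth[match(sc$stay_id, tabs$truth$stay_id), ]
  expect_equal(sc$n_measured, tr$n_measured)
  expect_equal(sc$n_deficits, tr$n_deficits)
  ok <- sc$eligible
  expect_true(any(ok))
  expect_equal(sc$score[ok], tr$true_score[ok])
  # injected window violations break the correspondence by making items missing
  cfgv <- sim_config(n_patients = 300, seed = 13, window_violation_frac = 0.2)
  tv <- generate_cohort(cfgv)
  sv <- compute_filab(tv$lab_events, tv$vitals, cfgv$registry,
                      stay_ids = tv$stays$stay_id)
  trv <- tv$truth[match(sv$stay_id, tv$truth$stay_id), ]
  expect_true(any(sv$n_measured < trv$n_measured))
})

test_that("tables round-trip through CSV and counts are bookkept", {
  tabs <- generate_cohort(sim_config(n_patients = 60, seed = 2))
  dir <- file.path(tempdir(), "filab_rt")
  write_tables(tabs, dir)
  back <- read_tables(dir)
  for (nm in c("stays", "lab_events", "vitals", "truth"))
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(tabs[[nm]]),
                 tolerance = 1e-8)
  # record rows equal the number of measured items
  expect_equal(nrow(tabs$lab_events) + nrow(tabs$vitals),
               sum(tabs$truth$n_measured))

  empty <- generate_cohort(sim_config(n_patients = 0, seed = 1))
  dir0 <- file.path(tempdir(), "filab_rt0")
  write_tables(empty, dir0)
  back0 <- read_tables(dir0)
  expect_equal(nrow(back0$stays), 0L)
  expect_equal(nrow(back0$lab_events), 0L)
})

test_that("a YAML configuration file round-trips into a valid config", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 25", "seed: 4", "abnormality_probs: 0.3",
               "beta_filab_per_0_1: 0.0"), tmp)
  cfg <- sim_config_from_yaml(tmp)
  expect_s3_class(cfg, "filab_sim_config")
  expect_equal(cfg$n_patients, 25L)
  expect_equal(unname(cfg$abnormality_probs[1]), 0.3)
  cfg2 <- sim_config_from_yaml(tmp, n_patients = 10)
  expect_equal(cfg2$n_patients, 10L)
})
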