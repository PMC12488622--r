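test_that("Cox fit recovers a known two-group rate ratio", {
  set.seed(41)
  n <- 10000
  grp <- rbinom(n, 1, 0.5)
  t_death <- rexp(n, 0.05 * 2^grp)
  co <- data.frame(filab_score = grp * 0.1,  # per-0.1 coding makes HR = rate ratio
                   time_28d = t_death, death_28d = 1L)
  fit <- fit_cox(co, "mortality_28d", model = "unadjusted")
  tr <- fit$terms
  expect_equal(nrow(tr), 1L)
  expect_true(tr$ci_low < 2 && 2 < tr$ci_high)
  expect_lt(abs(log(tr$hr) - log(2)), 0.1)
  expect_equal(fit$n_events, n)
})

test_that("degenerate exposures and empty event sets are refused", {
  co <- data.frame(filab_score = rep(0.4, 50), time_28d = rexp(50, 0.1),
                   death_28d = 1L)
  expect_error(fit_cox(co, "mortality_28d", model = "unadjusted"), "degenerate")
  co2 <- data.frame(filab_score = runif(50), time_28d = 28, death_28d = 0L)
  expect_error(fit_cox(co2, "mortality_28d", model = "unadjusted"), "no events")
})

test_that("tertile coding has an exact reference and an ordinal trend test", {
  set.seed(42)
  tabs <- generate_cohort(sim_config(n_patients = 4000, seed = 42))
  co <- cbind(tabs$stays, filab_score = tabs$truth$true_score)
  fit <- fit_cox(co, "mortality_28d", exposure = "tertiles",
                 model = "unadjusted")
  tr <- fit$terms
  expect_equal(tr$term[1:3], c("T1", "T2", "T3"))
  expect_equal(tr$hr[1], 1)
  expect_true(is.na(tr$ci_low[1]) && is.na(tr$p[1]))
  expect_true(all(tr$hr[2:3] > 0))
  expect_true(all(tr$ci_low[2:3] < tr$hr[2:3] & tr$hr[2:3] < tr$ci_high[2:3]))
  # monotone risk by construction -> T3 above T2, strong trend
  expect_gt(tr$hr[3], tr$hr[2])
  expect_lt(fit$p_trend, 0.001)
  # adjusted models nest and record their covariate sets
  sets <- model_covariates()
  expect_true(all(sets$model1 %in% sets$model2))
  expect_true(all(sets$model2 %in% sets$model3))
  fit3 <- fit_cox(co, "mortality_28d", model = "model3")
  expect_equal(fit3$covariates, sets$model3)
  expect_true(is.finite(fit3$terms$hr[1]))
})

test_that("RCS curve is centered at the reference and flags injected curvature", {
  set.seed(43)
  co <- sim_surv_cohort(8000, beta_per01 = log(1.4))
  r <- fit_rcs(co, "mortality_28d", covariates = character(0))
  expect_equal(predict(r, r$reference), 1)
  expect_equal(length(r$knots), 4L)
  expect_true(all(diff(r$curve$exposure) > 0))
  expect_true(all(r$curve$ci_low <= r$curve$hr & r$curve$hr <= r$curve$ci_high))
  expect_error(fit_rcs(co, "mortality_28d", n_knots = 2), "at least 3")

  # a strong quadratic bump in the log hazard must be detected
  s <- runif(8000)
  lp <- 4 * (s - 0.5)^2
  t_death <- rexp(8000, 0.01 * exp(lp))
  cq <- data.frame(filab_score = s, time_28d = pmin(t_death, 28),
                   death_28d = as.integer(t_death <= 28))
  rq <- fit_rcs(cq, "mortality_28d", covariates = character(0))
  expect_lt(rq$p_nonlinearity, 0.001)
})

test_that("Kaplan-Meier matches the hand product-limit and log-rank oracles", {
  # one group, hand product-limit: events at 1 and 2, censor at 3
  co <- data.frame(filab_score = c(0.1, 0.2, 0.3),
                   time_28d = c(1, 2, 3), death_28d = c(1L, 1L, 0L),
                   grp = "all")
  km <- km_logrank(co, "grp", "mortality_28d")
  expect_equal(km_survival_at(km, "all", c(1, 2, 3)), c(2 / 3, 1 / 3, 1 / 3))
  expect_true(is.na(km$p))
  # with a censor at 2 the risk set at t = 3 is one subject, so S(3) drops to 0
  coc <- data.frame(filab_score = 1:3 / 10, time_28d = c(1, 2, 3),
                    death_28d = c(1L, 0L, 1L), grp = "all")
  kmc <- km_logrank(coc, "grp", "mortality_28d")
  expect_equal(km_survival_at(kmc, "all", c(1, 3)), c(2 / 3, 0))

  # two identical groups: statistic 0, p = 1
  co2 <- rbind(transform(co, grp = "a"), transform(co, grp = "b"))
  km2 <- km_logrank(co2, "grp", "mortality_28d")
  expect_equal(km2$chisq, 0, tolerance = 1e-10)
  expect_equal(km2$p, 1)

  # 20-patient two-group fixture vs the brute-force hypergeometric sum
  set.seed(44)
  co3 <- data.frame(filab_score = runif(20),
                    time_28d = sample(1:12, 20, replace = TRUE),
                    death_28d = rbinom(20, 1, 0.7),
                    grp = rep(c("a", "b"), each = 10))
  km3 <- km_logrank(co3, "grp", "mortality_28d")
  oracle <- logrank_bruteforce(co3$time_28d, co3$death_28d, co3$grp)
  expect_equal(km3$chisq, oracle, tolerance = 1e-8)
  # KM at the horizon equals 1 - event proportion without censoring
  co4 <- data.frame(filab_score = runif(50), time_28d = runif(50, 1, 27),
                    death_28d = 1L, grp = "g")
  km4 <- km_logrank(co4, "grp", "mortality_28d")
  expect_equal(km_survival_at(km4, "g", 28), 0)
})

test_that("subgroup analysis reports strata, flags degeneracies, finds interactions", {
  set.seed(45)
  n <- 20000
  s <- pmin(pmax(rnorm(n, 0.48, 0.087), 0), 1)
  male <- rbinom(n, 1, 0.45)
  # sex-specific log-HRs per 0.1 unit differing by 0.5
  lp <- (0.1 + 0.5 * male) * s / 0.1
  t_death <- rexp(n, 0.0013 * exp(lp))
  co <- data.frame(filab_score = s, sex = ifelse(male == 1, "male", "female"),
                   time_28d = pmin(t_death, 28),
                   death_28d = as.integer(t_death <= 28))
  strat <- list(sex = list(split = function(d) factor(d$sex), drop = "sex"))
  res <- subgroup_analysis(co, "mortality_28d", stratifiers = strat,
                           covariates = character(0))
  expect_equal(nrow(res), 2L)
  expect_true(all(res$estimable))
  expect_lt(res$p_interaction[1], 0.01)
  expect_gt(res$hr[res$level == "male"], res$hr[res$level == "female"])

  # constant stratifier -> single stratum, no interaction, still reported
  co$onearm <- "yes"
  strat2 <- list(onearm = list(split = function(d) factor(d$onearm),
                               drop = character(0)))
  res2 <- subgroup_analysis(co, "mortality_28d", stratifiers = strat2,
                            covariates = character(0))
  expect_equal(nrow(res2), 1L)
  expect_true(is.na(res2$p_interaction))

  # stratum with zero events is non-estimable, not fatal
  co3 <- co[1:2000, ]
  co3$death_28d[co3$sex == "female"] <- 0L
  res3 <- suppressWarnings(subgroup_analysis(co3, "mortality_28d",
                                             stratifiers = strat,
                                             covariates = character(0)))
  expect_false(res3$estimable[res3$level == "female"])
  expect_true(res3$estimable[res3$level == "male"])
})
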