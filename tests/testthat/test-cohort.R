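filab_row <- function(stay_id, score = 0.4, eligible = TRUE) {
  data.frame(stay_id = stay_id, n_items_total = 33L,
             n_measured = if (eligible) 30L else 15L,
             n_missing = if (eligible) 3L else 18L,
             n_deficits = 12L, score = if (eligible) score else NA_real_,
             eligible = eligible, stringsAsFactors = FALSE)
}

test_that("exclusion cascade removes one stay per violated rule, in order", {
  stays <- rbind(clean_stay("ok"),
                 clean_stay("rep", is_first_icu_stay = 0L),
                 clean_stay("young", age = 16),
                 clean_stay("short", icu_los = 0.5),
                 clean_stay("preg", pregnant = 1L),
                 clean_stay("sparse"))
  scores <- rbind(filab_row("ok"), filab_row("rep"), filab_row("young"),
                  filab_row("short"), filab_row("preg"),
                  filab_row("sparse", eligible = FALSE))
  res <- apply_filters(stays, scores)
  expect_equal(nrow(res$cohort), 1L)
  expect_equal(res$cohort$stay_id, "ok")
  expect_equal(sum(res$log$n_removed), 5L)
  expect_equal(res$log$n_remaining[nrow(res$log)], 1L)
  # the log is a consistent cascade: initial n - removals = final n
  expect_true(all(diff(res$log$n_remaining) <= 0))
  expect_equal(nrow(stays) - sum(res$log$n_removed), nrow(res$cohort))
  # missing required fields are their own rule
  st2 <- rbind(clean_stay("ok"), clean_stay("norr", respiratory_rate = NA))
  sc2 <- rbind(filab_row("ok"), filab_row("norr"))
  res2 <- apply_filters(st2, sc2)
  expect_equal(res2$log$n_removed[res2$log$rule == "missing_required"], 1L)
})

test_that("cascade is a pass-through on clean data and idempotent", {
  stays <- do.call(rbind, lapply(sprintf("s%d", 1:8), clean_stay))
  scores <- do.call(rbind, lapply(stays$stay_id, filab_row))
  res <- apply_filters(stays, scores)
  expect_equal(nrow(res$cohort), 8L)
  expect_true(all(res$log$n_removed == 0L))
  again <- apply_filters(res$cohort, scores)
  expect_true(all(again$log$n_removed == 0L))
  expect_equal(nrow(again$cohort), nrow(res$cohort))
  expect_error(apply_filters(stays, scores[-1, ]), "without a FI-Lab result")
})

test_that("injected under-18 violations are removed at the configured rate", {
  cfg <- sim_config(n_patients = 2000, seed = 31,
                    filter_violation_fracs = c(age_under_18 = 0.10,
                                               los_under_24h = 0, pregnancy = 0,
                                               repeat_stay = 0,
                                               excess_missing_items = 0,
                                               missing_required = 0))
  tabs <- generate_cohort(cfg)
  sc <- compute_filab(tabs$lab_events, tabs$vitals, cfg$registry,
                      stay_ids = tabs$stays$stay_id)
  res <- apply_filters(tabs$stays, sc)
  removed <- res$log$n_removed[res$log$rule == "age_under_18"]
  expect_lt(abs(removed - 200), 3 * sqrt(2000 * 0.1 * 0.9))
})

test_that("ridge chained imputation recovers exact linear structure", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  d$y[5] <- NA
  out <- impute_covariates(d)
  expect_lt(abs(out$y[5] - 10), 0.1)
  expect_equal(out$y[-5], d$y[-5])  # observed cells untouched
  expect_equal(out$x, d$x)

  full <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_identical(impute_covariates(full), full)

  allna <- data.frame(a = 1:5, b = NA_real_)
  expect_error(impute_covariates(allna), "entirely missing")
  chrna <- data.frame(a = c(1, NA, 3), b = c("x", NA, "z"),
                      stringsAsFactors = FALSE)
  expect_error(impute_covariates(chrna), "non-numeric")
})

test_that("imputation beats the marginal spread on correlated Gaussian data", {
  set.seed(77)
  n <- 5000
  x <- rnorm(n)
  y <- 0.9 * x + rnorm(n, sd = sqrt(1 - 0.81))
  z <- 0.5 * x + rnorm(n, sd = 0.8)
  d <- data.frame(x = x, y = y, z = z)
  miss <- sample(n, n * 0.05)
  d$y[miss] <- NA
  out <- impute_covariates(d)
  rmse <- sqrt(mean((out$y[miss] - y[miss])^2))
  expect_lt(rmse, sd(y))
  # and specifically better than mean imputation
  expect_lt(rmse, sqrt(mean((mean(d$y, na.rm = TRUE) - y[miss])^2)))
})

test_that("sparse missingness routes below-threshold variables to row removal", {
  d <- data.frame(a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  d$a[1:3] <- NA     # 0.3% -> complete-case rows
  d$b[1:50] <- NA    # 5%   -> left for imputation
  res <- drop_sparse_missing(d)
  expect_equal(nrow(res$cohort), 997L)
  expect_equal(sum(is.na(res$cohort$a)), 0L)
  expect_gt(sum(is.na(res$cohort$b)), 0L)
  rep <- res$report
  expect_true(rep$handled[rep$variable == "a"])
  expect_false(rep$handled[rep$variable == "b"])
  # column mode drops the variable instead
  resc <- drop_sparse_missing(d, action = "columns")
  expect_false("a" %in% names(resc$cohort))
  expect_equal(nrow(resc$cohort), 1000L)
  # fully complete table is untouched
  full <- data.frame(u = 1:5, v = 6:10)
  expect_equal(drop_sparse_missing(full)$cohort, full)
})

test_that("VIF matches its closed form and flags collinearity", {
  set.seed(5)
  n <- 500
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  res <- vif_screen(X)
  expect_true(all(res$vif < 1.2))
  expect_false(any(res$flagged))

  dup <- cbind(X, d = X$a)
  resd <- vif_screen(dup)
  expect_true(is.infinite(resd$vif[resd$variable == "a"]))
  expect_true(all(resd$flagged[resd$variable %in% c("a", "d")]))

  # correlation ~0.8 -> VIF near 1/(1-0.64) = 2.78, from the closed form
  Y <- data.frame(x1 = rnorm(n))
  Y$x2 <- 0.8 * Y$x1 + sqrt(1 - 0.64) * rnorm(n)
  resy <- vif_screen(Y)
  r2 <- cor(Y$x1, Y$x2)^2
  expect_equal(resy$vif, rep(1 / (1 - r2), 2), tolerance = 1e-8)
  expect_lt(abs(resy$vif[1] - 2.78), 0.8)
  expect_true(all(resy$flagged == (resy$vif > 2)))

  # agrees with the standard regression-diagnostic implementation
  skip_if_not_installed("car")
  set.seed(6)
  Z <- data.frame(p = rnorm(n), q = rnorm(n))
  Z$r <- 0.6 * Z$p - 0.3 * Z$q + rnorm(n)
  yresp <- rnorm(n)
  ref <- car::vif(lm(yresp ~ p + q + r, data = Z))
  expect_equal(vif_screen(Z)$vif, unname(ref[c("p", "q", "r")]),
               tolerance = 1e-8)
})
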