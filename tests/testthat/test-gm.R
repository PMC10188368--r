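test_that("D0-1 weighting hits the reference ratio exactly and conserves flow", {
  # d2 = 96 against 60 deaths on days 2-6: r = 1.6, w = 1.5, new d2 = 144
  counts <- fixture_counts(deaths = c(50, 96, 20, 15, 10, 9, 6, 4, 2, 1),
                           total = 5000)
  res <- apply_d01_weighting(counts, weight_constant = 2.4)
  expect_equal(res$weight, 1.5)
  expect_equal(res$counts$deaths[2], 144)
  expect_equal(ratio_metrics(res$counts)$values$d01_d26, 2.4)
  expect_equal(attr(res$counts, "effective_weight_d01"), 1.5)
  # flow conservation still holds after rebalancing
  expect_silent(perimort:::validate_interval_counts(res$counts))
  # downstream deaths untouched
  expect_equal(res$counts$deaths[3:10], counts$deaths[3:10])

  # at or above the constant the table is unchanged with weight 1
  high <- fixture_counts(deaths = c(50, 120, 10, 10, 10, 5, 5, 4, 2, 1),
                         total = 5000) # r = 3.0
  res_high <- apply_d01_weighting(high)
  expect_equal(res_high$weight, 1)
  expect_equal(res_high$counts$deaths, high$deaths)

  # zero D0-1 deaths: degenerate, unweighted, flagged
  zero <- fixture_counts(deaths = c(50, 0, 4, 3, 1, 1, 1, 0, 0, 0),
                         total = 5000)
  res_zero <- apply_d01_weighting(zero)
  expect_true(res_zero$degenerate)
  expect_equal(res_zero$counts$deaths[2], 0)
  expect_true(is.na(res_zero$weight))

  # zero D2-6 deaths: weighting undefined
  nod26 <- fixture_counts(deaths = c(50, 20, 0, 0, 0, 0, 0, 2, 1, 0),
                          total = 5000)
  expect_error(apply_d01_weighting(nod26), "undefined")
})

test_that("cohort-inflation balancing leaves downstream intervals untouched", {
  counts <- fixture_counts(deaths = c(50, 96, 20, 15, 10, 9, 6, 4, 2, 1),
                           total = 5000)
  res <- apply_d01_weighting(counts, balance = "inflate-cohort")
  expect_equal(res$counts$deaths[2], 144)
  expect_equal(attr(res$counts, "total_pregnancies"), 5048)
  expect_equal(res$counts$entrants[3:10], counts$entrants[3:10])
  expect_silent(perimort:::validate_interval_counts(res$counts))
})

test_that("the stillbirth constraint is exact on the hazard-ratio scale", {
  # observed stillbirth/D0-1 ratio of 1.0 triggers the constraint
  counts <- fixture_counts(deaths = c(100, 100, 22, 16, 11, 8, 5, 8, 3, 2),
                           total = 8000)
  expect_equal(ratio_metrics(counts)$values$sb_d01, 1.0)
  fit <- fit_gm(counts, adjust_config(model = 2))
  expect_true(fit$constraint_active)
  expect_equal(fitted_sb_ratio(fit), 1.89, tolerance = 1e-9)
  expect_equal(coef(fit)[["gamma1"]] - coef(fit)[["gamma2"]], log(1.89),
               tolerance = 1e-12)
  # gamma2 is anchored on the D0-1 data, so the adjusted stillbirth risk is
  # the reference multiple of the D0-1 cumulative hazard
  q2 <- counts$deaths[2] / counts$entrants[2]
  expect_equal(fit$lifetable$q[2], q2)
  expect_equal(fit$lifetable$q[1], 1 - (1 - q2)^1.89, tolerance = 1e-10)
})

test_that("the constraint is skipped when the observed ratio is already plausible", {
  counts <- fixture_counts(deaths = c(250, 100, 22, 16, 11, 8, 5, 8, 3, 2),
                           total = 8000) # ratio 2.5 >= 1.89
  fit <- fit_gm(counts, adjust_config(model = 2))
  expect_false(fit$constraint_active)
  expect_true(any(grepl("skipped", fit$flags)))
  m1 <- fit_gm(counts, adjust_config(model = 1))
  expect_equal(fit$lifetable$q[1], m1$lifetable$q[1], tolerance = 1e-10)
  expect_equal(fit$lifetable$q[2], m1$lifetable$q[2], tolerance = 1e-10)
})

test_that("the smooth tail matches a brute-force constrained-MLE grid search", {
  # heaped day 7: days 5-9 hold 4, 4, 12, 2, 3 deaths
  counts <- fixture_counts(deaths = c(60, 90, 30, 20, 14, 4, 4, 12, 2, 3),
                           total = 8000)
  fit <- fit_gm(counts, adjust_config(model = 2))
  co <- coef(fit)
  coarse <- grid_search_tail(
    counts,
    gamma0_grid = seq(0, 2e-3, length.out = 21),
    alpha_grid = seq(-9, -3, length.out = 25),
    beta_grid = seq(-1.5, 0.2, length.out = 25)
  )
  # optimizer attains at least the best grid likelihood
  d <- counts$deaths[3:10]; n <- counts$entrants[3:10]
  x <- seq(2.5, 9.5, by = 1)
  h_fit <- co[["gamma0"]] + exp(co[["alpha"]] + co[["beta"]] * x)
  ll_fit <- sum(ifelse(d > 0, d * log(-expm1(-h_fit)), 0) + (n - d) * (-h_fit))
  expect_gte(ll_fit, coarse$value - 1e-6)
  # smoothing flattens the day-7 heap into the plausible band
  expect_lt(fit$expected_deaths[["D7"]], 12)
  expect_gte(fit$fitted_heaping, 0.8)
  expect_lte(fit$fitted_heaping, 1.3)
})

test_that("fitted heaping lands in the plausible band across heaped inputs (property)", {
  heaps <- list(c(4, 4, 12, 2, 3), c(2, 2, 20, 1, 1), c(6, 5, 9, 4, 3),
                c(0, 3, 15, 2, 0))
  for (h in heaps) {
    counts <- fixture_counts(deaths = c(60, 90, 30, 20, 14, h), total = 8000)
    fit <- fit_gm(counts, adjust_config(model = 2))
    expect_gte(fit$fitted_heaping, 0.8)
    expect_lte(fit$fitted_heaping, 1.3)
  }
})

test_that("unconstrained log-likelihood dominates the constrained one", {
  for (seed in c(21, 22, 23)) {
    counts <- random_counts(seed, n = 6000)
    q <- quality_report(counts)
    if (!isTRUE(q$triggers$sb_constraint)) next
    ll_free <- fit_gm(counts, adjust_config(model = 3), q)$loglik
    ll_con <- fit_gm(counts, adjust_config(model = 2), q)$loglik
    expect_gte(ll_free, ll_con)
  }
})

test_that("adjust_survey runs the four models with the documented interplay", {
  # a table whose observed ratios put both triggers on: stillbirth/D0-1 of
  # 100/96 ~ 1.04 < 1.89 and D0-1/D2-6 of 96/60 = 1.6 < 2.4
  counts <- fixture_counts(deaths = c(100, 96, 20, 15, 10, 9, 6, 8, 3, 2),
                           total = 8000)
  adj <- adjust_survey(counts)

  expect_named(adj$fits, paste0("model", 1:4))
  r <- adj$rates
  sbr <- function(m) r$sbr[r$model == m]
  enmr <- function(m) r$enmr[r$model == m]
  # model 3 never moves the stillbirth rate
  expect_equal(sbr("model3"), sbr("model1"), tolerance = 1e-10)
  # both triggers fire here: orderings follow
  expect_true(adj$quality$triggers$sb_constraint)
  expect_true(adj$quality$triggers$d01_weight)
  expect_gte(sbr("model4"), sbr("model2"))
  expect_gte(sbr("model2"), sbr("model1"))
  expect_gte(enmr("model3"), enmr("model1"))
  # relative differences against model 1
  expect_equal(adj$relative_diff$sbr[adj$relative_diff$model == "model1"], 0)
  expect_equal(
    adj$relative_diff$sbr[adj$relative_diff$model == "model2"],
    100 * (sbr("model2") - sbr("model1")) / sbr("model1")
  )
})

test_that("model-3 stillbirth neutrality holds across random tables (property)", {
  for (seed in c(41, 42, 43, 44)) {
    preset <- survey_preset("probable", n_pregnancies = 8000)
    sim <- simulate_cohort(preset$cohort, seed = seed)
    corrupted <- inject_reporting_errors(sim$records, preset$errors,
                                         seed = seed + 1000)
    counts <- build_interval_counts(corrupted$records)
    adj <- adjust_survey(counts, models = c(1, 3))
    r <- adj$rates
    expect_equal(r$sbr[r$model == "model3"], r$sbr[r$model == "model1"],
                 tolerance = 1e-10)
  }
})

test_that("with no triggered adjustment all four models agree on the stillbirth rate", {
  preset <- survey_preset("plausible", n_pregnancies = 20000)
  sim <- simulate_cohort(preset$cohort, seed = 51)
  counts <- build_interval_counts(sim$records)
  adj <- adjust_survey(counts)
  if (!adj$quality$triggers$sb_constraint && !adj$quality$triggers$d01_weight) {
    expect_equal(max(adj$rates$sbr) - min(adj$rates$sbr), 0, tolerance = 1e-9)
  }
  # smoothing may move the daily risks, but rates stay close to observed
  expect_equal(adj$rates$pmr[adj$rates$model == "model4"],
               adj$rates$pmr[adj$rates$model == "model1"], tolerance = 0.05)
})

test_that("relative differences use the per-survey definition", {
  # (25.6 - 12.2) / 12.2 = 109.8%
  expect_equal(100 * (25.6 - 12.2) / 12.2, 109.83606557, tolerance = 1e-8)
  counts <- fixture_counts(deaths = c(100, 100, 22, 16, 11, 8, 5, 8, 3, 2),
                           total = 8000)
  adj <- adjust_survey(counts, models = c(1, 2))
  r <- adj$rates
  rd <- adj$relative_diff
  expect_equal(rd$pmr[rd$model == "model2"],
               100 * (r$pmr[2] - r$pmr[1]) / r$pmr[1])
})

test_that("a failing model leaves the others intact", {
  # no deaths on days 2-6 makes models 3/4 weighting undefined
  counts <- fixture_counts(deaths = c(50, 20, 0, 0, 0, 0, 0, 2, 1, 0),
                           total = 5000)
  adj <- adjust_survey(counts)
  expect_true("model1" %in% names(adj$fits))
  expect_true("model2" %in% names(adj$fits))
  expect_true(length(adj$errors) >= 1 || all(paste0("model", 3:4) %in% names(adj$fits)))
})

test_that("gm_fit methods expose coefficients, likelihood, fitted values, residuals", {
  counts <- fixture_counts(deaths = c(60, 90, 30, 20, 14, 4, 4, 12, 2, 3),
                           total = 8000)
  fit <- fit_gm(counts, adjust_config(model = 2))
  expect_named(coef(fit), c("gamma1", "gamma2", "gamma0", "alpha", "beta"))
  expect_s3_class(fitted(fit), "life_table")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  res <- residuals(fit)
  expect_length(res, 10)
  # response residuals sum observed-minus-expected deaths
  resp <- residuals(fit, type = "response")
  expect_equal(unname(resp[3]),
               counts$deaths[3] - fit$lifetable$q[3] * counts$entrants[3])
})
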