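test_that("ratio-consistent default hazards place the true ratios at the constants", {
  h <- ratio_consistent_hazards()
  p_sb <- 0.025
  # expected-count ratios, computed from first principles
  e_sb <- p_sb
  e_d01 <- (1 - p_sb) * h[["d01"]]
  e_d26 <- (1 - p_sb) * (1 - h[["d01"]]) *
    (1 - prod(1 - h[paste0("d", 2:6)]))
  expect_equal(e_sb / e_d01, 1.89, tolerance = 1e-10)
  expect_equal(e_d01 / e_d26, 2.4, tolerance = 1e-8)
  # daily risks decline
  expect_true(all(diff(h[paste0("d", 2:9)]) < 0))
  tr <- true_rates(cohort_params())
  expect_equal(tr$sbr, 25)
  expect_equal(round(tr$enmr, 1), 19.2)
  expect_equal(round(tr$pmr, 1), 43.7)
})

test_that("simulation is deterministic under a fixed seed", {
  params <- cohort_params(n_pregnancies = 800)
  a <- simulate_cohort(params, seed = 5)
  b <- simulate_cohort(params, seed = 5)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records,
                         simulate_cohort(params, seed = 6)$records))
  errs <- survey_preset("probable")$errors
  ca <- inject_reporting_errors(a$records, errs, seed = 9)
  cb <- inject_reporting_errors(b$records, errs, seed = 9)
  expect_identical(ca$records, cb$records)
  expect_identical(ca$ledger, cb$ledger)
})

test_that("sampled stillbirth rate stays within binomial error of the truth", {
  n <- 1e5
  params <- cohort_params(
    n_pregnancies = n, stillbirth_risk = 0.025,
    daily_hazards = stats::setNames(rep(0, 9), c("d01", paste0("d", 2:9))),
    ongoing_fraction = 0
  )
  sim <- simulate_cohort(params, seed = 12)
  counts <- build_interval_counts(sim$records)
  sbr_hat <- 1000 * counts$deaths[1] / counts$entrants[1]
  se <- 1000 * sqrt(0.025 * 0.975 / n)
  expect_lt(abs(sbr_hat - 25), 3 * se)
  # zero hazards: no neonatal deaths, everyone alive
  expect_equal(sum(counts$deaths[2:10]), 0)
  expect_equal(sum(sim$records$outcome == "livebirth" &
                     !sim$records$child_alive, na.rm = TRUE), 0)
})

test_that("records produced by the generator pass the full records pipeline", {
  sim <- simulate_cohort(cohort_params(n_pregnancies = 1500), seed = 77)
  path <- tempfile(fileext = ".csv")
  write_pregnancy_table(sim$records, path)
  back <- read_pregnancy_table(path)
  expect_equal(nrow(back), nrow(sim$records))
  elig <- apply_eligibility(back)
  expect_equal(sum(elig$exclusions), 0) # generator only emits eligible records
  expect_equal(as.data.frame(build_interval_counts(elig$records)),
               as.data.frame(build_interval_counts(sim$records)))
})

test_that("error injection conserves records and zero errors are the identity", {
  sim <- simulate_cohort(cohort_params(n_pregnancies = 3000), seed = 21)
  none <- inject_reporting_errors(sim$records, reporting_errors(), seed = 22)
  expect_identical(none$records, sim$records)
  expect_true(all(none$ledger$action == "keep"))

  errs <- survey_preset("improbable")$errors
  corrupted <- inject_reporting_errors(sim$records, errs, seed = 23)
  omitted <- sum(corrupted$ledger$action == "omitted")
  expect_equal(nrow(corrupted$records), nrow(sim$records) - omitted)
  # the ledger covers every input record exactly once
  expect_setequal(corrupted$ledger$record_id, sim$records$record_id)
})

test_that("extreme error settings behave as their definitions demand", {
  sim <- simulate_cohort(cohort_params(n_pregnancies = 4000), seed = 31)
  # all stillbirths omitted
  all_omit <- inject_reporting_errors(
    sim$records, reporting_errors(p_sb_omit = 1), seed = 32)
  expect_equal(sum(all_omit$records$outcome == "stillbirth"), 0)

  # certain heaping from day 5 with deaths only on day 5
  h <- stats::setNames(c(0.02, 0, 0, 0, 0.05, 0, 0, 0, 0),
                       c("d01", paste0("d", 2:9)))
  sim5 <- simulate_cohort(
    cohort_params(n_pregnancies = 4000, daily_hazards = h), seed = 33)
  heaped <- inject_reporting_errors(
    sim5$records,
    reporting_errors(p_heap = c(day5 = 1, day6 = 0, day8 = 0, day9 = 0)),
    seed = 34)
  counts <- build_interval_counts(heaped$records)
  expect_equal(counts$deaths[6], 0)                 # day 5 emptied
  expect_gt(counts$deaths[8], 0)                    # onto day 7
  expect_equal(ratio_metrics(counts)$values$heaping, 5)

  # stillbirth-to-day-0 transference moves counts between the two intervals;
  # a large cohort keeps the binomial noise on the moved fraction small
  big <- simulate_cohort(cohort_params(n_pregnancies = 40000), seed = 36)
  sim <- big
  base_counts <- build_interval_counts(sim$records)
  trans <- inject_reporting_errors(
    sim$records, reporting_errors(p_d0_to_sb = 0.3), seed = 35)
  tcounts <- build_interval_counts(trans$records)
  moved <- sum(trans$ledger$action == "d01_to_stillbirth")
  expect_equal(tcounts$deaths[1], base_counts$deaths[1] + moved)
  expect_equal(tcounts$deaths[2], base_counts$deaths[2] - moved)
  # in expectation the corrupted ratio is (SB + 0.3 D01) / (0.7 D01)
  expected <- (base_counts$deaths[1] + 0.3 * base_counts$deaths[2]) /
    (0.7 * base_counts$deaths[2])
  expect_equal(ratio_metrics(tcounts)$values$sb_d01, expected,
               tolerance = 0.15)
})

test_that("a one-replicate recovery run is reproducible and well-formed", {
  rec1 <- recovery_experiment(cohort_params(n_pregnancies = 2000),
                              survey_preset("probable")$errors,
                              n_reps = 1, seed = 99)
  rec2 <- recovery_experiment(cohort_params(n_pregnancies = 2000),
                              survey_preset("probable")$errors,
                              n_reps = 1, seed = 99)
  expect_equal(rec1$estimates, rec2$estimates)
  expect_equal(rec1$summary, rec2$summary)
  expect_equal(rec1$n_failed, 0)
  expect_true(all(c("model", "rate", "bias", "rmse") %in%
                    names(rec1$summary)))
})

test_that("with no reporting errors model 1 is nearly unbiased", {
  rec <- recovery_experiment(
    cohort_params(n_pregnancies = 5000),
    reporting_errors(), n_reps = 20, seed = 17)
  s <- rec$summary
  pmr_bias_m1 <- s$bias[s$model == "model1" & s$rate == "pmr"]
  # Monte-Carlo error for 20 reps of 5000: generous envelope
  expect_lt(abs(pmr_bias_m1), 2)
  # stillbirth rate untouched by weighting even here
  expect_equal(s$mean_estimate[s$model == "model3" & s$rate == "sbr"],
               s$mean_estimate[s$model == "model1" & s$rate == "sbr"],
               tolerance = 1e-8)
})

test_that("simulation configs load from JSON with presets and explicit blocks", {
  cfg <- tempfile(fileext = ".json")
  writeLines('{"cohort": {"n_pregnancies": 1234}, "errors": "probable"}', cfg)
  sc <- read_sim_config(cfg)
  expect_equal(sc$cohort$n_pregnancies, 1234L)
  expect_equal(sc$errors$p_sb_omit, survey_preset("probable")$errors$p_sb_omit)

  cfg2 <- tempfile(fileext = ".yaml")
  writeLines(c("errors:", "  p_sb_omit: 0.5"), cfg2)
  sc2 <- read_sim_config(cfg2)
  expect_equal(sc2$errors$p_sb_omit, 0.5)
  expect_equal(sc2$cohort$n_pregnancies, cohort_params()$n_pregnancies)
})
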