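# Shared fixtures, built in code.

# A well-behaved mid-size survey table: 1000 pregnancies, 20 stillbirths,
# declining daily deaths, mild day-7 bump.
fixture_counts <- function(deaths = c(20, 25, 10, 7, 5, 4, 3, 6, 2, 1),
                           total = 1000, censored = NULL) {
  interval_counts(deaths = deaths, total = total, censored = censored,
                  survey_id = "fixture")
}

# Random plausible-scale tables drawn through the cohort generator, so they
# always satisfy the accounting invariants.
random_counts <- function(seed, n = 2000) {
  sim <- simulate_cohort(cohort_params(n_pregnancies = n), seed = seed)
  build_interval_counts(sim$records)
}

# A small hand-written pregnancy table in the documented CSV layout.
fixture_records_csv <- function(path = tempfile(fileext = ".csv"),
                                lines = NULL) {
  if (is.null(lines)) {
    lines <- c(
      "survey_id,record_id,gestation_months,conception_offset_months,outcome,child_alive,age_at_death_days,current_age_months,weight",
      "s1,r1,9,24,livebirth,true,,15,1.5",
      "s1,r2,9,30,stillbirth,,,,1.0",
      "s1,r3,9,12,livebirth,false,0,,0.8"
    )
  }
  writeLines(lines, path)
  path
}

# Brute-force constrained-MLE grid search over the smooth-tail parameters
# (gamma0, alpha, beta); independent check that the optimizer finds the
# likelihood optimum.
grid_search_tail <- function(counts, gamma0_grid, alpha_grid, beta_grid) {
  d <- counts$deaths[3:10]
  n <- counts$entrants[3:10]
  x <- seq(2.5, 9.5, by = 1)
  best <- list(value = -Inf, par = NULL)
  for (g0 in gamma0_grid) for (a in alpha_grid) for (b in beta_grid) {
    h <- g0 + exp(a + b * x)
    q <- -expm1(-h)
    ll <- sum(ifelse(d > 0, d * log(q), 0) + (n - d) * (-h))
    if (is.finite(ll) && ll > best$value) {
      best <- list(value = ll, par = c(g0, a, b))
    }
  }
  best
}
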