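test_that("percentages round half away from zero to one decimal", {
  expect_identical(round_half_up(28.56, 1), 28.6)
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(-0.25, 1), -0.3)
  expect_identical(round_half_up(2.45, 1), 2.5)
})

test_that("suppression masks exactly the cells with 0 < n < 6", {
  expect_identical(suppress_cells(c(0L, 1L, 5L, 6L, 120L)),
                   c("0", "suppressed", "suppressed", "6", "120"))
})

test_that("the product-limit estimate matches hand calculations", {
  km <- km_estimate(c(1, 2), c(1, 0))
  expect_equal(km_surv_at(km, 1), 0.5)
  expect_equal(km_surv_at(km, 2), 0.5)
  # all censored: survival stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # survival starts at 1, is non-increasing, within [0, 1]
  set.seed(11)
  km3 <- km_estimate(sample(1:5, 20, TRUE), sample(0:1, 20, TRUE))
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
})

test_that("the estimator equals the brute-force life table on random small samples", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    times <- sample(1:4, n, replace = TRUE) # tie-rich
    events <- sample(0:1, n, replace = TRUE)
    km <- km_estimate(times, events)
    grid <- sort(unique(times))
    expect_equal(km_surv_at(km, grid), km_oracle_surv(times, events, grid),
                 tolerance = 1e-12)
  }
})

test_that("incidence rates are count per population times 100,000", {
  out <- biopsy_incidence(tibble::tibble(
    year = c(2002, 2003), n_biopsies = c(66, 0), population = c(1150000, 1200000)
  ))
  expect_identical(out$rate_per_100k, c(5.7, 0))
  expect_error(
    biopsy_incidence(tibble::tibble(year = 2002, n_biopsies = 5, population = 0)),
    class = "glomreg_validation_error"
  )
})

test_that("descriptive table reproduces counts with suppression applied last", {
  run <- small_run()
  t1 <- descriptive_table(run$cohort)
  n_row <- t1[t1$variable == "n", ]
  cfg <- small_config()
  expect_identical(n_row$n[n_row$dx == "iga_nephropathy"], 12L)
  # percentages use the table's biopsy denominator
  denom <- sum(run$cohort$common_gn)
  expect_equal(n_row$pct[n_row$dx == "iga_nephropathy"], 100 * 12 / denom)
  # a suppressed display cell keeps its underlying numeric estimate
  kf <- t1[t1$variable == "kidney_failure", ]
  small_cells <- !is.na(kf$n) & kf$n > 0 & kf$n < 6
  expect_identical(kf$display[small_cells],
                   rep("suppressed", sum(small_cells)))
  expect_true(all(!is.na(kf$n[small_cells])))
  # empty diagnosis subset: empty table, no division by zero
  empty <- descriptive_table(run$cohort, dx_codes = character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("Cox fits report hazard ratios, AIC and concordance", {
  sim <- simulate_survival_cohort(800, hr = 2, seed = 5)
  cohort <- tibble::tibble(
    primary_dx = ifelse(sim$group == 1, "fsgs", "iga_nephropathy"),
    multi_dx = FALSE, kf_eligible = TRUE,
    time_to_kf_years = sim$time, event_kidney_failure = sim$event,
    time_to_death_years = sim$time, event_death = sim$event
  )
  fit <- cox_fit(cohort, "kidney_failure", covariates = "diagnosis",
                 dx_codes = c("iga_nephropathy", "fsgs"))
  td <- tidy(fit)
  expect_identical(td$term, "diagnosisfsgs")
  expect_true(td$conf.low < 2 & td$conf.high > 2) # truth inside the CI
  expect_true(td$conf.low < td$hr & td$hr < td$conf.high)
  g <- glance(fit)
  expect_identical(g$n, 800L)
  expect_true(g$concordance > 0.5)
  # dropping an informative covariate cannot improve (lower) the AIC
  # relative to the null partial likelihood
  aic_null <- -2 * fit$fit$loglik[1]
  expect_true(g$aic <= aic_null)
})

test_that("degenerate covariates are flagged and empty strata error", {
  cohort <- tibble::tibble(
    primary_dx = "iga_nephropathy", multi_dx = FALSE, kf_eligible = TRUE,
    time_to_kf_years = rexp(50) + 0.1,
    event_kidney_failure = rep(c(TRUE, FALSE), 25),
    time_to_death_years = 1, event_death = FALSE
  )
  expect_warning(
    cox_fit(cohort, "kidney_failure", covariates = "diagnosis",
            dx_codes = c("iga_nephropathy", "fsgs")),
    class = "glomreg_degenerate_covariate"
  )
  expect_error(
    cox_fit(cohort, "mortality", covariates = "diagnosis",
            dx_codes = c("iga_nephropathy", "fsgs")),
    class = "glomreg_model_error"
  )
})

test_that("per-diagnosis KM curves exclude multi-diagnosis and prevalent patients", {
  run <- full_run()
  curves <- km_curves(run$cohort, "kidney_failure")
  expect_true(all(curves$surv >= 0 & curves$surv <= 1))
  expect_setequal(unique(curves$primary_dx), common_gn_codes())
  for (d in unique(curves$primary_dx)) {
    s <- curves$surv[curves$primary_dx == d]
    expect_true(all(diff(s) <= 1e-12), info = d)
  }
})

test_that("plot constructors return ggplot objects", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_s3_class(autoplot(km), "ggplot")
  run <- small_run()
  fit <- tryCatch(cox_fit(run$cohort, "mortality", covariates = "diagnosis",
                          dx_codes = c("iga_nephropathy", "membranous_nephropathy")),
                  error = function(e) NULL)
  if (!is.null(fit)) expect_s3_class(plot_hazard_ratios(fit), "ggplot")
})
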