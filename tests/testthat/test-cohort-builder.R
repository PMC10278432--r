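mk_reports <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    biopsy_date = as.Date(vapply(rows, `[[`, "", 2)),
    primary_dx = vapply(rows, `[[`, "", 3) |> dplyr::na_if("NA"),
    diagnostic = vapply(rows, `[[`, "", 3) != "NA"
  )
}

test_that("linkage is by coverage membership with set semantics", {
  classified <- tibble::tibble(patient_id = c("a", "a", "b", "c"))
  admin <- list(coverage = tibble::tibble(
    patient_id = c("a", "a", "b"), # duplicate rows are idempotent
    start_date = as.Date("2000-01-01"), end_date = as.Date("2021-12-31")
  ))
  lk <- link_patients(classified, admin)
  expect_identical(lk$n_linked_individuals, 2L)
  expect_identical(lk$n_unlinked_individuals, 1L)
  expect_identical(nrow(lk$linked), 3L)
  empty <- link_patients(classified,
                         list(coverage = admin$coverage[0, ]))
  expect_identical(empty$n_linked_individuals, 0L)
})

test_that("index-biopsy selection follows the multi-biopsy rules", {
  # initial nondiagnostic: index moves to the first diagnostic biopsy
  a <- select_index_biopsies(mk_reports(
    c("p1", "2005-03-01", "NA"),
    c("p1", "2007-06-01", "iga_nephropathy")
  ))
  expect_identical(nrow(a), 1L)
  expect_identical(a$index_date, as.Date("2007-06-01"))

  # re-biopsy with a different diagnosis: two episodes, first censored
  b <- select_index_biopsies(mk_reports(
    c("p2", "2006-01-10", "membranous_nephropathy"),
    c("p2", "2010-04-20", "pauci_immune_gn")
  ))
  expect_identical(nrow(b), 2L)
  expect_identical(b$rebiopsy_censor_date[1], as.Date("2010-04-20"))
  expect_true(all(b$multi_dx))

  # repeat of the same diagnosis: only the index biopsy counts
  c_ <- select_index_biopsies(mk_reports(
    c("p3", "2008-02-01", "iga_nephropathy"),
    c("p3", "2012-09-01", "iga_nephropathy")
  ))
  expect_identical(nrow(c_), 1L)
  expect_identical(c_$index_date, as.Date("2008-02-01"))
  expect_false(c_$multi_dx[1])

  # later nondiagnostic biopsy is ignored
  d <- select_index_biopsies(mk_reports(
    c("p4", "2009-01-01", "lupus_nephritis"),
    c("p4", "2013-01-01", "NA")
  ))
  expect_identical(nrow(d), 1L)
  expect_true(is.na(d$rebiopsy_censor_date[1]))
})

test_that("lab attachment uses the closed +/-3-month window, nearest first", {
  ep <- tibble::tibble(patient_id = "p1", index_date = as.Date("2010-06-15"))
  labs <- tibble::tibble(
    patient_id = "p1",
    test = "eGFR",
    value = c(50, 70, 90),
    date = as.Date(c("2010-06-05", "2009-11-27", "2010-09-15"))
  )
  # -10 days beats -200 days (excluded) and the +3-month boundary value
  out <- attach_labs(ep, labs)
  expect_identical(out$egfr, 50)
  # the exact +3-month boundary date is included when it is the only lab
  out2 <- attach_labs(ep, labs[3, ])
  expect_identical(out2$egfr, 90)
  # nothing in window: missing
  out3 <- attach_labs(ep, labs[2, ])
  expect_true(is.na(out3$egfr))
  # exact distance tie breaks toward the pre-biopsy value
  tie <- tibble::tibble(
    patient_id = "p1", test = "eGFR", value = c(40, 60),
    date = as.Date(c("2010-06-10", "2010-06-20"))
  )
  expect_identical(attach_labs(ep, tie)$egfr, 40)
})

test_that("uPCR is converted before selection and the conversion is monotone", {
  expect_identical(pcr_to_acr(150), 150)
  x <- c(10, 50, 100, 400)
  conv <- pcr_to_acr(x, coef = c(intercept = -0.3, slope = 0.9))
  expect_true(all(diff(conv) > 0))
  expect_identical(pcr_to_acr(0), 0)
  expect_error(pcr_to_acr(-1), class = "glomreg_validation_error")

  ep <- tibble::tibble(patient_id = "p1", index_date = as.Date("2010-06-15"))
  labs <- tibble::tibble(patient_id = "p1", test = "uPCR", value = 150,
                         date = as.Date("2010-06-01"))
  expect_identical(attach_labs(ep, labs)$uacr, 150)
})

test_that("the weighted comorbidity index sums standard weights once each", {
  ep <- tibble::tibble(patient_id = "p1", index_date = as.Date("2010-06-15"))
  claims <- function(...) {
    conds <- c(..., character(0))
    tibble::tibble(patient_id = rep("p1", length(conds)),
                   condition_code = conds,
                   date = rep(as.Date("2009-01-01"), length(conds)))
  }
  expect_identical(compute_charlson(ep, claims())$charlson, 0L)
  expect_identical(
    compute_charlson(ep, claims("diabetes_complicated", "metastatic_tumor"))$charlson,
    8L
  )
  # repeated claims count once; hierarchy keeps the severe member
  expect_identical(
    compute_charlson(ep, claims("diabetes", "diabetes", "diabetes_complicated"))$charlson,
    2L
  )
  # a claim four years back is outside the three-year lookback
  old <- tibble::tibble(patient_id = "p1", condition_code = "chf",
                        date = as.Date("2006-06-14"))
  expect_identical(compute_charlson(ep, old)$charlson, 0L)
  # claims on the index date itself are excluded (half-open window)
  same_day <- tibble::tibble(patient_id = "p1", condition_code = "chf",
                             date = as.Date("2010-06-15"))
  expect_identical(compute_charlson(ep, same_day)$charlson, 0L)
})

test_that("medication flags use ATC prefixes in the half-open 6-month window", {
  ep <- tibble::tibble(patient_id = "p1", index_date = as.Date("2010-06-15"))
  disp <- function(code, days) {
    tibble::tibble(patient_id = "p1", atc_code = code,
                   date = as.Date("2010-06-15") + days)
  }
  out <- attach_medications(ep, disp("C09AA02", 30))
  expect_true(out$acei_arb)
  expect_false(out$statin)
  # +7 months is outside the window
  out2 <- attach_medications(ep, disp("C10AA01", 215))
  expect_false(out2$statin)
  # dispensation on the biopsy day itself does not count (open left edge)
  out3 <- attach_medications(ep, disp("C09AA02", 0))
  expect_false(out3$acei_arb)
  out4 <- attach_medications(ep, disp("C07AB02", 10))
  expect_true(out4$antihypertensive_non_raasi)
  out5 <- attach_medications(ep, disp("C09AA02", 30)[0, ])
  expect_false(any(out5$acei_arb, out5$statin, out5$antihypertensive_non_raasi))
})

test_that("outcomes are tracked independently with correct censoring", {
  mk_admin <- function(krt = NULL, death = NULL, cov_end = "2021-12-31") {
    list(
      coverage = tibble::tibble(patient_id = "p1",
                                start_date = as.Date("1992-01-01"),
                                end_date = as.Date(cov_end)),
      krt_events = if (is.null(krt)) {
        tibble::tibble(patient_id = character(), event = character(),
                       date = as.Date(character()))
      } else {
        tibble::tibble(patient_id = "p1", event = "dialysis_start",
                       date = as.Date(krt))
      },
      deaths = if (is.null(death)) {
        tibble::tibble(patient_id = character(),
                       death_date = as.Date(character()))
      } else {
        tibble::tibble(patient_id = "p1", death_date = as.Date(death))
      }
    )
  }
  ep <- tibble::tibble(patient_id = "p1", index_date = as.Date("2015-01-01"),
                       rebiopsy_censor_date = as.Date(NA))

  # dialysis at +2 years and death at +3.5 years: both events count
  both <- resolve_outcomes(ep, mk_admin(krt = "2017-01-01", death = "2018-07-01"))
  expect_true(both$event_kidney_failure)
  expect_true(both$event_death)
  expect_equal(both$time_to_kf_years, 2, tolerance = 0.01)
  expect_equal(both$time_to_death_years, 3.5, tolerance = 0.01)

  # coverage ends at +1.2 years with no events: censored for coverage loss
  cl <- resolve_outcomes(ep, mk_admin(cov_end = "2016-03-15"))
  expect_false(cl$event_kidney_failure)
  expect_identical(cl$censor_reason, "coverage_loss")
  expect_equal(cl$followup_years, 1.2, tolerance = 0.01)

  # event-free follow-up ends at the administrative study end
  se <- resolve_outcomes(ep, mk_admin())
  expect_identical(se$censor_reason, "study_end")
  expect_equal(se$followup_years,
               as.numeric(as.Date("2021-03-31") - as.Date("2015-01-01")) / 365.25)

  # dialysis before index: prevalent, excluded from kidney-failure analyses
  prev <- resolve_outcomes(ep, mk_admin(krt = "2014-01-01"))
  expect_true(prev$prevalent_krt)
  expect_false(prev$kf_eligible)

  # a kidney-failure event after the re-biopsy censor date does not count
  ep2 <- ep
  ep2$rebiopsy_censor_date <- as.Date("2016-01-01")
  reb <- resolve_outcomes(ep2, mk_admin(krt = "2017-01-01"))
  expect_false(reb$event_kidney_failure)
  expect_identical(reb$censor_reason, "rebiopsy_new_dx")
})

test_that("the built cohort respects follow-up bounds and is order-independent", {
  run <- small_run()
  cohort <- run$cohort
  expect_true(all(cohort$index_date + cohort$followup_years * 365.25 <=
                    as.Date("2021-04-01")))
  expect_true(all(cohort$followup_years >= 0))
  expect_true(all(cohort$time_to_kf_years <= cohort$followup_years + 1e-9))
  # shuffling the classified input rows does not change the cohort
  shuffled <- run$classified[rev(seq_len(nrow(run$classified))), ]
  cohort2 <- build_cohort(shuffled, run$admin)
  ord <- function(x) x[order(x$patient_id, x$index_date), ]
  expect_equal(ord(cohort2), ord(cohort), ignore_attr = TRUE)
})
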