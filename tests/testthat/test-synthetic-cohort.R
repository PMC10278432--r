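test_that("generated counts match the configuration exactly", {
  run <- small_run()
  cfg <- small_config()
  truth <- run$truth
  # per-diagnosis index episodes
  idx <- truth[truth$role == "index", ]
  for (d in names(cfg$diagnosis_counts)) {
    expect_identical(sum(idx$primary_dx == d, na.rm = TRUE),
                     as.integer(cfg$diagnosis_counts[[d]]), info = d)
  }
  # report arithmetic: episodes + repeats + nondiagnostic companions
  expect_identical(nrow(truth), 41L + 3L + 2L + 1L + 2L)
  expect_identical(sum(!truth$diagnostic), 2L + 1L + 2L)
  expect_identical(dplyr::n_distinct(truth$patient_id), 41L - 1L + 2L)
})

test_that("ground-truth invariants hold", {
  truth <- small_run()$truth
  diag <- truth[truth$diagnostic, ]
  expect_true(all(
    diag$glomeruli_global_sclerosis + diag$glomeruli_segmental_sclerosis <=
      diag$glomeruli_total
  ))
  # Oxford present iff IgA; lupus indices present iff lupus nephritis
  expect_identical(!is.na(diag$oxford_m), diag$primary_dx == "iga_nephropathy")
  expect_identical(!is.na(diag$ln_activity), diag$primary_dx == "lupus_nephritis")
  expect_true(all(is.na(truth$primary_dx[!truth$diagnostic])))
  # biopsy dates inside the study window
  cfg <- small_config()
  expect_true(all(truth$biopsy_date >= cfg$study_window[1]))
  expect_true(all(truth$biopsy_date <= cfg$study_window[2]))
})

test_that("administrative events stay inside coverage and deaths come last", {
  run <- small_run()
  admin <- run$admin
  cov <- admin$coverage
  inside <- function(tbl, date_col) {
    m <- match(tbl$patient_id, cov$patient_id)
    all(!is.na(m) & tbl[[date_col]] >= cov$start_date[m] &
          tbl[[date_col]] <= cov$end_date[m])
  }
  expect_true(inside(admin$labs, "date"))
  expect_true(inside(admin$dispensations, "date"))
  expect_true(inside(admin$claims, "date"))
  expect_true(inside(admin$krt_events, "date"))
  expect_true(inside(admin$deaths, "death_date"))
  # death, when present, is the patient's last recorded event
  for (i in seq_len(nrow(admin$deaths))) {
    pid <- admin$deaths$patient_id[i]
    others <- c(admin$krt_events$date[admin$krt_events$patient_id == pid])
    if (length(others) > 0) {
      expect_true(all(others <= admin$deaths$death_date[i]))
    }
  }
})

test_that("identical config and seed give identical output; seeds differ", {
  a <- generate_registry(small_config(seed = 7L))
  b <- generate_registry(small_config(seed = 7L))
  c <- generate_registry(small_config(seed = 8L))
  expect_identical(a$truth, b$truth)
  expect_identical(a$admin, b$admin)
  expect_identical(render_reports(a$truth, a$styles),
                   render_reports(b$truth, b$styles))
  expect_false(identical(a$truth, c$truth))
})

test_that("infeasible configurations fail with an informative error", {
  expect_error(
    registry_config(
      diagnosis_counts = c(iga_nephropathy = 3L),
      outcome_counts = tibble::tibble(dx = "iga_nephropathy",
                                      kidney_failure = 5L, death = 0L),
      female_counts = c(iga_nephropathy = 1L),
      era_counts = default_era_counts()[0, ],
      dual_dx_pairs = default_dual_dx_pairs()[0, ],
      n_repeat_same_dx = 0L, n_nondx_before = 0L, n_nondx_after = 0L,
      n_nondx_only = 0L, n_unlinked = 0L, n_coverage_loss = 0L,
      n_prevalent_krt = 0L
    ),
    class = "glomreg_config_error",
    regexp = "iga_nephropathy"
  )
})

test_that("an all-zero configuration yields empty outputs", {
  cfg <- registry_config(
    diagnosis_counts = c(iga_nephropathy = 0L),
    outcome_counts = default_outcome_counts()[0, ],
    female_counts = c(iga_nephropathy = 0L),
    era_counts = default_era_counts()[0, ],
    dual_dx_pairs = default_dual_dx_pairs()[0, ],
    n_repeat_same_dx = 0L, n_nondx_before = 0L, n_nondx_after = 0L,
    n_nondx_only = 0L, n_unlinked = 0L, n_coverage_loss = 0L,
    n_prevalent_krt = 0L
  )
  gen <- generate_registry(cfg)
  expect_identical(nrow(gen$truth), 0L)
  expect_identical(nrow(gen$admin$coverage), 0L)
  expect_identical(nrow(render_reports(gen$truth, gen$styles)), 0L)
})

test_that("rendered documents contain each fact exactly once", {
  run <- small_run()
  truth <- run$truth
  docs <- run$documents
  # global-sclerosis counts appear exactly once per diagnostic document
  for (i in which(truth$diagnostic)[1:10]) {
    v <- truth$glomeruli_global_sclerosis[i]
    hits <- stringr::str_count(tolower(docs$text[i]), "globally sclero")
    expect_identical(hits, 1L, info = docs$doc_id[i])
  }
  # dropped EM section means no effacement sentence and an NA truth value
  dropped <- run$styles$drop_em
  expect_true(all(is.na(truth$em_effacement_pct[dropped])))
  expect_false(any(grepl("effacement", docs$text[dropped], ignore.case = TRUE)))
})

test_that("nondiagnostic reports state inadequate sampling without a disease name", {
  run <- small_run()
  nd <- run$truth$doc_id[!run$truth$diagnostic]
  texts <- run$documents$text[match(nd, run$documents$doc_id)]
  expect_true(all(grepl("inadequate|insufficient|nondiagnostic",
                        texts, ignore.case = TRUE)))
  expect_false(any(grepl("nephropathy|nephritis|glomerulosclerosis",
                         texts, ignore.case = TRUE)))
})

test_that("the fixture corpus writes one file per report plus tables, reproducibly", {
  run <- small_run()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_corpus(run$documents, run$truth, run$admin, d1)
  m2 <- write_fixture_corpus(run$documents, run$truth, run$admin, d2)
  expect_identical(sum(grepl("reports/", m1$file)), nrow(run$truth))
  expect_identical(m1$md5, m2$md5)
  back <- read_corpus(d1)
  expect_identical(back$documents$text, run$documents$text)
  expect_identical(nrow(back$truth), nrow(run$truth))
})
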