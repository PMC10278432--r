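# Shared fixtures: a small seeded registry for unit tests and a memoized
# full-scale run for the end-to-end checks.

small_config <- function(seed = 42L) {
  registry_config(
    seed = seed,
    diagnosis_counts = c(
      iga_nephropathy = 12L, membranous_nephropathy = 8L,
      pauci_immune_gn = 6L, lupus_nephritis = 5L,
      diabetic_nephropathy = 6L, acute_tubular_injury = 4L
    ),
    outcome_counts = tibble::tibble(
      dx = c("iga_nephropathy", "membranous_nephropathy"),
      kidney_failure = c(4L, 2L),
      death = c(3L, 2L)
    ),
    female_counts = c(iga_nephropathy = 5L, membranous_nephropathy = 3L),
    era_counts = default_era_counts()[0, ],
    dual_dx_pairs = tibble::tibble(
      first_dx = "membranous_nephropathy", second_dx = "pauci_immune_gn"
    ),
    n_repeat_same_dx = 3L, n_nondx_before = 2L, n_nondx_after = 1L,
    n_nondx_only = 2L, n_unlinked = 3L, n_coverage_loss = 2L,
    n_prevalent_krt = 1L
  )
}

.fixture_cache <- new.env(parent = emptyenv())

small_run <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- run_registry_pipeline(
      small_config(), audit_n = 10, audit_min_per_year = 0, fit_models = FALSE
    )
  }
  .fixture_cache$small
}

full_run <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- run_registry_pipeline(registry_config())
  }
  .fixture_cache$full
}

# Independent brute-force product-limit oracle: a from-scratch life table
# evaluated at every distinct observed time (events tied with censorings
# keep the censored subjects in the risk set at that time).
km_oracle_surv <- function(times, events, eval_times) {
  ev_times <- sort(unique(times[events == 1]))
  vapply(eval_times, function(t0) {
    s <- 1
    for (te in ev_times[ev_times <= t0]) {
      n_risk <- sum(times >= te)
      d <- sum(times == te & events == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

km_surv_at <- function(km, eval_times) {
  # step-function evaluation of a km_estimate tibble
  vapply(eval_times, function(t0) {
    i <- which(km$time <= t0)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}
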