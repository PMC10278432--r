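#' Simulate a two-group exponential survival cohort
#'
#' Small seeded simulator used to validate the survival layer by parameter
#' recovery: exponential event times with a multiplicative hazard between
#' two groups, and independent exponential censoring.
#'
#' @param n Number of subjects.
#' @param hr True hazard ratio of group 1 vs group 0.
#' @param baseline_rate Baseline hazard (events per year) in group 0.
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param admin_cap Administrative censoring time (years).
#' @param seed Optional integer seed.
#' @return Tibble with `group`, `time`, `event`.
#' @export
simulate_survival_cohort <- function(n, hr = 2, baseline_rate = 0.2,
                                     censor_rate = 0.1, admin_cap = 10,
                                     seed = NULL) {
  draw <- function() {
    group <- stats::rbinom(n, 1, 0.5)
    rate <- baseline_rate * hr^group
    t_event <- stats::rexp(n, rate)
    t_cens <- pmin(stats::rexp(n, censor_rate), admin_cap)
    tibble::tibble(
      group = group,
      time = pmin(t_event, t_cens),
      event = t_event <= t_cens
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
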