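#' Weighted Charlson comorbidity index weights
#'
#' The classic 17-condition weighted index (1/2/3/6 weights). Condition
#' hierarchies (diabetes vs diabetes with complications, liver disease,
#' malignancy vs metastatic tumor) count only the more severe member.
#'
#' @return Named integer vector of weights.
#' @export
charlson_weights <- function() {
  c(
    mi = 1L, chf = 1L, pvd = 1L, cvd = 1L, dementia = 1L, copd = 1L,
    rheumatic = 1L, pud = 1L, mild_liver = 1L, diabetes = 1L,
    diabetes_complicated = 2L, hemiplegia = 2L, renal = 2L, malignancy = 2L,
    moderate_severe_liver = 3L, metastatic_tumor = 6L, aids = 6L
  )
}

# min over a possibly empty date vector without the base min() warning
min_date <- function(x) {
  if (length(x) == 0) as.Date(NA) else min(x)
}

charlson_hierarchy <- function() {
  list(
    c("diabetes", "diabetes_complicated"),
    c("mild_liver", "moderate_severe_liver"),
    c("malignancy", "metastatic_tumor")
  )
}

#' Link parsed biopsies to administrative coverage
#'
#' A patient links if and only if their health identifier appears in the
#' insurance coverage table (set semantics: duplicate coverage rows are
#' idempotent). Unlinked patients are excluded from the cohort and counted.
#'
#' @param classified Tibble from [classify_reports()] (needs `patient_id`).
#' @param admin Administrative bundle (list with a `coverage` tibble).
#' @return List: `linked` and `unlinked` report tibbles,
#'   `n_linked_individuals`, `n_unlinked_individuals`.
#' @export
link_patients <- function(classified, admin) {
  covered <- unique(admin$coverage$patient_id)
  hit <- classified$patient_id %in% covered
  list(
    linked = classified[hit, ],
    unlinked = classified[!hit, ],
    n_linked_individuals = dplyr::n_distinct(classified$patient_id[hit]),
    n_unlinked_individuals = dplyr::n_distinct(classified$patient_id[!hit])
  )
}

#' Select index biopsies under the multi-biopsy rules
#'
#' Applied per patient in date order: nondiagnostic biopsies never define an
#' episode (if the first biopsy is nondiagnostic the index moves to the
#' first diagnostic one, and later nondiagnostic biopsies are ignored);
#' repeat biopsies with the same diagnosis keep only the index; a re-biopsy
#' with a different diagnosis opens a new episode and the earlier episode is
#' censored at the re-biopsy date.
#'
#' @param linked Tibble of linked classified reports (needs `patient_id`,
#'   `biopsy_date`, `primary_dx`, `diagnostic`).
#' @return Tibble of index episodes with `index_date`,
#'   `rebiopsy_censor_date` and `multi_dx`.
#' @export
select_index_biopsies <- function(linked) {
  if (any(is.na(linked$biopsy_date[linked$diagnostic %in% TRUE]))) {
    rlang::abort("Diagnostic biopsy without a parseable date",
                 class = "glomreg_validation_error")
  }
  linked |>
    dplyr::filter(.data$diagnostic, !is.na(.data$primary_dx)) |>
    dplyr::arrange(.data$patient_id, .data$biopsy_date) |>
    dplyr::distinct(.data$patient_id, .data$primary_dx, .keep_all = TRUE) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$biopsy_date, .by_group = TRUE) |>
    dplyr::mutate(
      index_date = .data$biopsy_date,
      rebiopsy_censor_date = dplyr::lead(.data$biopsy_date),
      multi_dx = dplyr::n() > 1
    ) |>
    dplyr::ungroup()
}

#' Convert urine protein-to-creatinine ratio to albumin-to-creatinine ratio
#'
#' Pluggable monotone log-linear conversion
#' `uACR = exp(intercept + slope * log(uPCR))` (mg/mmol in, mg/mmol out).
#' The default coefficients are the identity; published conversion
#' coefficients can be supplied through `coef`.
#'
#' @param upcr Non-negative numeric vector (mg/mmol).
#' @param coef Named numeric vector `c(intercept, slope)`, `slope > 0`.
#' @return Converted uACR values (mg/mmol).
#' @export
pcr_to_acr <- function(upcr, coef = c(intercept = 0, slope = 1)) {
  if (any(upcr < 0, na.rm = TRUE)) {
    rlang::abort("uPCR must be non-negative", class = "glomreg_validation_error")
  }
  if (coef[["slope"]] <= 0) {
    rlang::abort("Conversion slope must be positive for monotonicity")
  }
  if (coef[["intercept"]] == 0 && coef[["slope"]] == 1) return(upcr)
  out <- exp(coef[["intercept"]] + coef[["slope"]] * log(upcr))
  out[!is.na(upcr) & upcr == 0] <- 0
  out
}

#' Attach laboratory values in the biopsy window
#'
#' Candidate laboratory results are restricted to the closed window
#' `[index - window_months, index + window_months]` (calendar months);
#' urine PCR results are converted to uACR before selection. The result
#' nearest the index date wins; exact ties break toward the pre-biopsy
#' value.
#'
#' @param episodes Episode tibble (needs `patient_id`, `index_date`).
#' @param labs Laboratory tibble (`patient_id`, `test`, `value`, `date`).
#' @param window_months Window half-width in calendar months.
#' @param pcr_coef Conversion coefficients passed to [pcr_to_acr()].
#' @return `episodes` with `egfr` and `uacr` columns added (`NA` = no lab
#'   in window; such rows drop out of complete-case models).
#' @export
attach_labs <- function(episodes, labs, window_months = 3,
                        pcr_coef = c(intercept = 0, slope = 1)) {
  labs <- labs |>
    dplyr::mutate(
      value = ifelse(.data$test == "uPCR",
                     pcr_to_acr(.data$value, pcr_coef), .data$value),
      test = ifelse(.data$test == "uPCR", "uACR", .data$test)
    )
  pick <- function(test_name) {
    episodes |>
      dplyr::select("patient_id", "index_date") |>
      dplyr::inner_join(labs[labs$test == test_name, ],
                        by = "patient_id", relationship = "many-to-many") |>
      dplyr::filter(
        .data$date >= .data$index_date %m-% lubridate::period(window_months, units = "month"),
        .data$date <= .data$index_date %m+% lubridate::period(window_months, units = "month")
      ) |>
      dplyr::mutate(dist = abs(as.numeric(.data$date - .data$index_date))) |>
      dplyr::arrange(.data$dist, .data$date) |>
      dplyr::distinct(.data$patient_id, .data$index_date, .keep_all = TRUE) |>
      dplyr::select("patient_id", "index_date", "value")
  }
  egfr <- pick("eGFR") |> dplyr::rename(egfr = "value")
  uacr <- pick("uACR") |> dplyr::rename(uacr = "value")
  episodes |>
    dplyr::left_join(egfr, by = c("patient_id", "index_date")) |>
    dplyr::left_join(uacr, by = c("patient_id", "index_date"))
}

#' @importFrom lubridate %m-% %m+%
NULL

#' Compute the weighted Charlson comorbidity index
#'
#' Conditions are ascertained from diagnostic claims in the half-open
#' lookback window `[index - lookback_years, index)`; each condition counts
#' once, hierarchies keep the more severe member, and standard weights are
#' summed.
#'
#' @param episodes Episode tibble (`patient_id`, `index_date`).
#' @param claims Claims tibble (`patient_id`, `condition_code`, `date`).
#' @param weights Named weight vector, see [charlson_weights()].
#' @param lookback_years Lookback in years.
#' @return `episodes` with a `charlson` column (0 when no qualifying claim).
#' @export
compute_charlson <- function(episodes, claims, weights = charlson_weights(),
                             lookback_years = 3) {
  eligible <- episodes |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::inner_join(claims, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(
      .data$date >= .data$index_date %m-% lubridate::period(lookback_years, units = "year"),
      .data$date < .data$index_date
    ) |>
    dplyr::distinct(.data$patient_id, .data$index_date, .data$condition_code)
  unknown <- setdiff(unique(eligible$condition_code), names(weights))
  if (length(unknown) > 0) {
    rlang::warn(paste0("Ignoring unknown condition code(s): ",
                       paste(unknown, collapse = ", ")))
    eligible <- eligible[eligible$condition_code %in% names(weights), ]
  }
  # hierarchy: drop the milder member when both are present
  for (h in charlson_hierarchy()) {
    severe <- eligible |>
      dplyr::filter(.data$condition_code == h[2]) |>
      dplyr::select("patient_id", "index_date") |>
      dplyr::mutate(.drop_mild = TRUE)
    eligible <- eligible |>
      dplyr::left_join(severe, by = c("patient_id", "index_date")) |>
      dplyr::filter(!(dplyr::coalesce(.data$.drop_mild, FALSE) &
                        .data$condition_code == h[1])) |>
      dplyr::select(-".drop_mild")
  }
  scores <- eligible |>
    dplyr::mutate(w = weights[.data$condition_code]) |>
    dplyr::group_by(.data$patient_id, .data$index_date) |>
    dplyr::summarise(charlson = sum(.data$w), .groups = "drop")
  episodes |>
    dplyr::left_join(scores, by = c("patient_id", "index_date")) |>
    dplyr::mutate(charlson = as.integer(dplyr::coalesce(.data$charlson, 0L)))
}

#' Default ATC prefixes for the medication classes
#' @return Named list of regex prefixes.
#' @export
default_atc_classes <- function() {
  list(
    acei_arb = "^C09",
    statin = "^C10AA",
    antihypertensive_non_raasi = "^C0[2378]"
  )
}

#' Flag medication classes dispensed after biopsy
#'
#' A class flag is true iff at least one dispensation with a matching ATC
#' prefix falls in the half-open window `(index, index + window_months]`
#' (calendar months).
#'
#' @param episodes Episode tibble (`patient_id`, `index_date`).
#' @param dispensations Tibble (`patient_id`, `atc_code`, `date`).
#' @param window_months Window length in calendar months.
#' @param classes Named list of ATC regex prefixes.
#' @return `episodes` with one logical column per class.
#' @export
attach_medications <- function(episodes, dispensations, window_months = 6,
                               classes = default_atc_classes()) {
  in_window <- episodes |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::inner_join(dispensations, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(
      .data$date > .data$index_date,
      .data$date <= .data$index_date %m+% lubridate::period(window_months, units = "month")
    )
  out <- episodes
  for (cl in names(classes)) {
    hits <- in_window |>
      dplyr::filter(stringr::str_detect(.data$atc_code, classes[[cl]])) |>
      dplyr::distinct(.data$patient_id, .data$index_date) |>
      dplyr::mutate(.hit = TRUE)
    out <- out |>
      dplyr::left_join(hits, by = c("patient_id", "index_date")) |>
      dplyr::mutate(!!cl := dplyr::coalesce(.data$.hit, FALSE)) |>
      dplyr::select(-".hit")
  }
  out
}

#' Resolve outcomes and censoring
#'
#' Kidney failure is the earliest dialysis start or transplant after the
#' index date; death comes from vital statistics. The two endpoints are
#' tracked independently: death censors the kidney-failure timeline but
#' kidney failure does not end mortality follow-up. Follow-up ends at the
#' earliest of the outcome, a re-biopsy with a different diagnosis, loss of
#' coverage, or the administrative study end. Patients with a
#' kidney-replacement event on or before the index date are flagged
#' prevalent and excluded from kidney-failure analyses.
#'
#' @param episodes Episode tibble (needs `patient_id`, `index_date`,
#'   `rebiopsy_censor_date`).
#' @param admin Administrative bundle (uses `krt_events`, `deaths`,
#'   `coverage`).
#' @param follow_up_end Administrative end of follow-up (Date).
#' @return `episodes` with event dates/indicators, follow-up times in years
#'   (days/365.25), `censor_reason` (kidney-failure timeline) and
#'   `kf_eligible`.
#' @export
resolve_outcomes <- function(episodes, admin,
                             follow_up_end = as.Date("2021-03-31")) {
  krt <- admin$krt_events |>
    dplyr::filter(.data$event %in% c("dialysis_start", "transplant"))
  first_krt_after <- episodes |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::inner_join(krt, by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date > .data$index_date) |>
    dplyr::group_by(.data$patient_id, .data$index_date) |>
    dplyr::summarise(kf_date = min_date(.data$date), .groups = "drop")
  prevalent <- episodes |>
    dplyr::select("patient_id", "index_date") |>
    dplyr::inner_join(krt, by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date <= .data$index_date) |>
    dplyr::distinct(.data$patient_id, .data$index_date) |>
    dplyr::mutate(prevalent_krt = TRUE)
  cov_end <- admin$coverage |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(coverage_end = max(.data$end_date), .groups = "drop")
  deaths <- admin$deaths |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(death_date = min_date(.data$death_date), .groups = "drop")

  out <- episodes |>
    dplyr::left_join(first_krt_after, by = c("patient_id", "index_date")) |>
    dplyr::left_join(prevalent, by = c("patient_id", "index_date")) |>
    dplyr::left_join(cov_end, by = "patient_id") |>
    dplyr::left_join(deaths, by = "patient_id") |>
    dplyr::mutate(
      prevalent_krt = dplyr::coalesce(.data$prevalent_krt, FALSE),
      kf_eligible = !.data$prevalent_krt,
      admin_end = pmin(
        dplyr::coalesce(.data$rebiopsy_censor_date, follow_up_end),
        dplyr::coalesce(.data$coverage_end, follow_up_end),
        follow_up_end
      ),
      end_death = pmin(dplyr::coalesce(.data$death_date, .data$admin_end),
                       .data$admin_end),
      event_death = !is.na(.data$death_date) & .data$death_date <= .data$admin_end,
      end_kf = pmin(dplyr::coalesce(.data$kf_date, .data$end_death),
                    .data$end_death),
      event_kidney_failure = !is.na(.data$kf_date) & .data$kf_date <= .data$end_death,
      followup_years = as.numeric(.data$end_death - .data$index_date) / 365.25,
      time_to_kf_years = as.numeric(.data$end_kf - .data$index_date) / 365.25,
      time_to_death_years = .data$followup_years,
      censor_reason = dplyr::case_when(
        .data$event_kidney_failure ~ "none",
        .data$event_death & .data$end_kf == .data$end_death ~ "death",
        !is.na(.data$rebiopsy_censor_date) &
          .data$end_kf == .data$rebiopsy_censor_date ~ "rebiopsy_new_dx",
        !is.na(.data$coverage_end) & .data$coverage_end < follow_up_end &
          .data$end_kf == .data$coverage_end ~ "coverage_loss",
        TRUE ~ "study_end"
      )
    ) |>
    dplyr::select(-"admin_end", -"end_death", -"end_kf")
  out
}

#' Build the analysis cohort
#'
#' Runs linkage, index-biopsy selection, covariate attachment (labs in the
#' biopsy window, weighted Charlson index over the claims lookback,
#' medication flags, census socioeconomic variables) and outcome resolution,
#' yielding one analysis row per index biopsy episode.
#'
#' @param classified Tibble from [classify_reports()].
#' @param admin Administrative bundle from [generate_registry()] (or read
#'   from disk).
#' @param follow_up_end Administrative end of follow-up.
#' @param lab_window_months,med_window_months,charlson_lookback_years
#'   Covariate window parameters (calendar months / years).
#' @param pcr_coef uPCR-to-uACR conversion coefficients ([pcr_to_acr()]).
#' @return Cohort tibble, one row per episode, with an attribute
#'   `"linkage"` holding the linkage counts.
#' @export
build_cohort <- function(classified, admin,
                         follow_up_end = as.Date("2021-03-31"),
                         lab_window_months = 3,
                         med_window_months = 6,
                         charlson_lookback_years = 3,
                         pcr_coef = c(intercept = 0, slope = 1)) {
  lk <- link_patients(classified, admin)
  episodes <- select_index_biopsies(lk$linked)
  if (nrow(episodes) == 0) {
    out <- episodes
    attr(out, "linkage") <- lk[c("n_linked_individuals", "n_unlinked_individuals")]
    return(out)
  }
  episodes <- attach_labs(episodes, admin$labs, lab_window_months, pcr_coef)
  episodes <- compute_charlson(episodes, admin$claims,
                               lookback_years = charlson_lookback_years)
  episodes <- attach_medications(episodes, admin$dispensations,
                                 med_window_months)
  episodes <- episodes |>
    dplyr::left_join(admin$census, by = "patient_id")
  episodes <- resolve_outcomes(episodes, admin, follow_up_end)
  episodes$age_at_biopsy <- floor(as.numeric(
    lubridate::interval(episodes$dob, episodes$index_date) / lubridate::years(1)
  ))
  cols <- c(
    "patient_id", "doc_id", "index_date", "primary_dx", "secondary_dx",
    "broad_group", "common_gn", "multi_dx", "age_at_biopsy", "sex", "egfr",
    "uacr", "charlson", "ses_quintile", "dwelling", "acei_arb", "statin",
    "antihypertensive_non_raasi", "event_kidney_failure", "kf_date",
    "event_death", "death_date", "time_to_kf_years", "time_to_death_years",
    "followup_years", "censor_reason", "kf_eligible", "rebiopsy_censor_date"
  )
  out <- episodes[, intersect(cols, names(episodes))]
  attr(out, "linkage") <- lk[c("n_linked_individuals", "n_unlinked_individuals")]
  out
}
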