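#' Round half away from zero
#'
#' Matches the rounding used in published descriptive tables (28.56 -> 28.6),
#' unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Small-cell suppression for count displays
#'
#' Any count with `0 < n < threshold` renders as `"suppressed"`; zero and
#' counts at or above the threshold render as-is. Suppression affects
#' display strings only, never underlying estimates.
#'
#' @param n Integer vector of cell counts.
#' @param display Display strings to use for unsuppressed cells (defaults to
#'   the counts themselves).
#' @param threshold Suppression threshold.
#' @return Character vector.
#' @export
suppress_cells <- function(n, display = as.character(n), threshold = 6) {
  ifelse(!is.na(n) & n > 0 & n < threshold, "suppressed", display)
}

fmt1 <- function(x) format(round_half_up(x, 1), nsmall = 1, trim = TRUE)

count_block <- function(cohort, dx_codes, variable, flag, denom, threshold) {
  n <- vapply(dx_codes, function(d) {
    sum(flag[cohort$primary_dx == d], na.rm = TRUE)
  }, 1L)
  pct <- 100 * n / denom
  tibble::tibble(
    variable = variable, level = NA_character_, dx = dx_codes,
    n = as.integer(n), pct = pct,
    display = suppress_cells(n, paste0(n, " (", fmt1(pct), ")"), threshold)
  )
}

cont_block <- function(cohort, dx_codes, variable, values, kind, threshold) {
  purrr::map_dfr(dx_codes, function(d) {
    v <- values[cohort$primary_dx == d]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      disp <- NA_character_
    } else if (kind == "mean_sd") {
      disp <- paste0(fmt1(mean(v)), " ± ", fmt1(stats::sd(v)))
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 2)
      disp <- paste0(fmt1(q[2]), " (", fmt1(q[1]), "-", fmt1(q[3]), ")")
    }
    tibble::tibble(
      variable = variable, level = kind, dx = d, n = length(v),
      pct = NA_real_, display = disp
    )
  })
}

#' Descriptive characteristics table
#'
#' One column per diagnosis: N (%), year-of-diagnosis eras, age (mean +/-
#' SD), female sex, eGFR and urine ACR (median, IQR), dwelling,
#' socioeconomic quintile, medication classes, comorbidity score and
#' follow-up (median, IQR), and the two outcomes. Normality routing is
#' fixed per variable (age is the only mean +/- SD variable). Cells with
#' 0 < n < `suppress_below` display as "suppressed"; percentages use the
#' table's biopsy denominator. Suppression is applied last and affects the
#' `display` column only.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param dx_codes Diagnosis columns to tabulate (default: the eight common
#'   glomerular diseases).
#' @param suppress_below Suppression threshold.
#' @return Long tibble: `variable`, `level`, `dx`, `n`, `pct`, `display`.
#' @export
descriptive_table <- function(cohort, dx_codes = common_gn_codes(),
                              suppress_below = 6) {
  sub <- cohort[cohort$primary_dx %in% dx_codes, ]
  denom <- nrow(sub)
  if (denom == 0) {
    return(tibble::tibble(variable = character(), level = character(),
                          dx = character(), n = integer(), pct = numeric(),
                          display = character()))
  }
  th <- suppress_below
  blocks <- list()

  n_dx <- vapply(dx_codes, function(d) sum(sub$primary_dx == d), 1L)
  blocks$n <- tibble::tibble(
    variable = "n", level = NA_character_, dx = dx_codes,
    n = as.integer(n_dx), pct = 100 * n_dx / denom,
    display = suppress_cells(n_dx, paste0(n_dx, " (", fmt1(100 * n_dx / denom), ")"), th)
  )

  era <- cut(lubridate::year(sub$index_date), c(-Inf, 2006, 2012, Inf),
             labels = c("2002-2006", "2007-2012", "2013-2019"))
  for (lev in levels(era)) {
    nb <- vapply(dx_codes, function(d) {
      sum(era[sub$primary_dx == d] == lev, na.rm = TRUE)
    }, 1L)
    pct <- 100 * nb / n_dx
    blocks[[paste0("era_", lev)]] <- tibble::tibble(
      variable = "year_of_diagnosis", level = lev, dx = dx_codes,
      n = as.integer(nb), pct = pct,
      display = suppress_cells(nb, paste0(nb, " (", fmt1(pct), ")"), th)
    )
  }

  blocks$age <- cont_block(sub, dx_codes, "age_years", sub$age_at_biopsy,
                           "mean_sd", th)
  fem <- count_block(sub, dx_codes, "female_sex", sub$sex == "F", n_dx, th)
  fem$pct <- 100 * fem$n / n_dx
  fem$display <- suppress_cells(fem$n, paste0(fem$n, " (", fmt1(fem$pct), ")"), th)
  blocks$female <- fem
  blocks$egfr <- cont_block(sub, dx_codes, "egfr", sub$egfr, "median_iqr", th)
  blocks$uacr <- cont_block(sub, dx_codes, "uacr", sub$uacr, "median_iqr", th)

  for (lev in c("rural", "urban")) {
    nb <- vapply(dx_codes, function(d) {
      sum(sub$dwelling[sub$primary_dx == d] == lev, na.rm = TRUE)
    }, 1L)
    blocks[[paste0("dwelling_", lev)]] <- tibble::tibble(
      variable = "dwelling", level = lev, dx = dx_codes, n = as.integer(nb),
      pct = 100 * nb / n_dx,
      display = suppress_cells(nb, paste0(nb, " (", fmt1(100 * nb / n_dx), ")"), th)
    )
  }
  for (q in 1:5) {
    nb <- vapply(dx_codes, function(d) {
      sum(sub$ses_quintile[sub$primary_dx == d] == q, na.rm = TRUE)
    }, 1L)
    blocks[[paste0("ses_", q)]] <- tibble::tibble(
      variable = "ses_quintile", level = as.character(q), dx = dx_codes,
      n = as.integer(nb), pct = 100 * nb / n_dx,
      display = suppress_cells(nb, paste0(nb, " (", fmt1(100 * nb / n_dx), ")"), th)
    )
  }
  for (med in c("antihypertensive_non_raasi", "acei_arb", "statin")) {
    nb <- vapply(dx_codes, function(d) {
      sum(sub[[med]][sub$primary_dx == d], na.rm = TRUE)
    }, 1L)
    blocks[[med]] <- tibble::tibble(
      variable = med, level = NA_character_, dx = dx_codes,
      n = as.integer(nb), pct = 100 * nb / n_dx,
      display = suppress_cells(nb, paste0(nb, " (", fmt1(100 * nb / n_dx), ")"), th)
    )
  }
  blocks$charlson <- cont_block(sub, dx_codes, "comorbidities", sub$charlson,
                                "median_iqr", th)
  blocks$followup <- cont_block(sub, dx_codes, "followup_years",
                                sub$followup_years, "median_iqr", th)

  for (oc in c("event_death", "event_kidney_failure")) {
    nm <- if (oc == "event_death") "all_cause_mortality" else "kidney_failure"
    nb <- vapply(dx_codes, function(d) {
      sum(sub[[oc]][sub$primary_dx == d], na.rm = TRUE)
    }, 1L)
    blocks[[nm]] <- tibble::tibble(
      variable = nm, level = NA_character_, dx = dx_codes,
      n = as.integer(nb), pct = 100 * nb / n_dx,
      display = suppress_cells(nb, paste0(nb, " (", fmt1(100 * nb / n_dx), ")"), th)
    )
  }
  out <- dplyr::bind_rows(blocks)
  for (cl in names(out)) out[[cl]] <- unname(out[[cl]])
  out
}

#' Biopsy incidence per 100,000
#'
#' Population denominators are external inputs supplied by the caller.
#'
#' @param counts Tibble with columns `year`, `n_biopsies`, `population`.
#' @return The input with a `rate_per_100k` column (one decimal).
#' @export
biopsy_incidence <- function(counts) {
  stopifnot(all(c("year", "n_biopsies", "population") %in% names(counts)))
  if (any(counts$population <= 0)) {
    rlang::abort("Population denominators must be positive",
                 class = "glomreg_validation_error")
  }
  counts$rate_per_100k <- round_half_up(
    counts$n_biopsies / counts$population * 1e5, 1
  )
  counts
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps the product-limit estimator: censored observations tied with
#' events at the same time remain in the risk set for that time (the
#' standard convention). Survival starts at 1 and is non-increasing.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return A tibble of class `glomreg_km` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @examples
#' km_estimate(c(1, 2), c(1, 0))
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  sf <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv
  )
  class(out) <- c("glomreg_km", class(out))
  attr(out, "n") <- length(times)
  out
}

#' Kaplan-Meier curves per diagnosis
#'
#' @param cohort Cohort tibble.
#' @param outcome `"kidney_failure"` or `"mortality"`.
#' @param dx_codes Diagnoses to include.
#' @param include_multi_dx Keep patients with more than one primary
#'   diagnosis? Excluded by default, matching the published design.
#' @return Tibble of per-diagnosis KM estimates (long format).
#' @export
km_curves <- function(cohort, outcome = c("kidney_failure", "mortality"),
                      dx_codes = common_gn_codes(),
                      include_multi_dx = FALSE) {
  outcome <- match.arg(outcome)
  sub <- cohort[cohort$primary_dx %in% dx_codes, ]
  if (!include_multi_dx) sub <- sub[!sub$multi_dx, ]
  if (outcome == "kidney_failure") sub <- sub[sub$kf_eligible, ]
  purrr::map_dfr(unique(sub$primary_dx), function(d) {
    s <- sub[sub$primary_dx == d, ]
    tm <- if (outcome == "kidney_failure") s$time_to_kf_years else s$time_to_death_years
    ev <- if (outcome == "kidney_failure") s$event_kidney_failure else s$event_death
    keep <- !is.na(tm) & tm > 0
    est <- km_estimate(tm[keep], ev[keep])
    est$primary_dx <- d
    tibble::as_tibble(est)
  })
}

#' Cox proportional-hazards model for registry outcomes
#'
#' Fits the published model form: diagnosis indicators (reference: IgA
#' nephropathy) with optional adjustment for age at biopsy, sex (reference
#' female), eGFR and log urine ACR. Complete cases only; individuals with
#' more than one primary diagnosis are excluded; patients with prevalent
#' kidney-replacement therapy are excluded from the kidney-failure model.
#' Ties use the Efron approximation.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param outcome `"kidney_failure"` or `"mortality"`.
#' @param covariates Any of `"diagnosis"`, `"age"`, `"sex"`, `"egfr"`,
#'   `"log_uacr"`.
#' @param reference_dx Reference diagnosis category.
#' @param dx_codes Diagnosis universe for the model.
#' @return An object of class `glomreg_cox` with the fit, AIC and Harrell's
#'   concordance; see [tidy.glomreg_cox()] and [glance.glomreg_cox()].
#' @export
cox_fit <- function(cohort, outcome = c("kidney_failure", "mortality"),
                    covariates = c("diagnosis", "age", "sex", "egfr", "log_uacr"),
                    reference_dx = "iga_nephropathy",
                    dx_codes = common_gn_codes()) {
  outcome <- match.arg(outcome)
  covariates <- match.arg(covariates, several.ok = TRUE)
  sub <- cohort[cohort$primary_dx %in% dx_codes & !cohort$multi_dx, ]
  if (outcome == "kidney_failure") sub <- sub[sub$kf_eligible, ]
  df <- tibble::tibble(
    time = if (outcome == "kidney_failure") sub$time_to_kf_years else sub$time_to_death_years,
    event = if (outcome == "kidney_failure") sub$event_kidney_failure else sub$event_death
  )
  if ("diagnosis" %in% covariates) {
    df$diagnosis <- factor(sub$primary_dx,
                           levels = c(reference_dx,
                                      setdiff(dx_codes, reference_dx)))
  }
  if ("age" %in% covariates) df$age <- sub$age_at_biopsy
  if ("sex" %in% covariates) df$sex <- factor(sub$sex, levels = c("F", "M"))
  if ("egfr" %in% covariates) df$egfr <- sub$egfr
  if ("log_uacr" %in% covariates) {
    df$log_uacr <- ifelse(sub$uacr > 0, log(sub$uacr), NA_real_)
  }
  df <- df[stats::complete.cases(df) & df$time > 0, ]
  if (nrow(df) == 0) {
    rlang::abort("No complete cases available for the model",
                 class = "glomreg_model_error")
  }
  if (sum(df$event) == 0) {
    rlang::abort("No outcome events in the analysis set",
                 class = "glomreg_model_error")
  }
  for (cv in setdiff(names(df), c("time", "event"))) {
    if (dplyr::n_distinct(df[[cv]]) < 2) {
      rlang::warn(paste0("Covariate '", cv, "' is constant; its hazard ",
                         "ratio is degenerate"),
                  class = "glomreg_degenerate_covariate")
    }
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ .,
    data = df, ties = "efron", x = FALSE, y = TRUE
  )
  structure(
    list(
      fit = fit, outcome = outcome, covariates = covariates,
      reference_dx = reference_dx, n = nrow(df), n_event = sum(df$event),
      aic = stats::AIC(fit),
      concordance = unname(summary(fit)$concordance["C"])
    ),
    class = "glomreg_cox"
  )
}

#' @export
print.glomreg_cox <- function(x, ...) {
  cat("<glomreg_cox> outcome:", x$outcome, "\n")
  cat("  n =", x$n, " events =", x$n_event, "\n")
  cat("  AIC =", fmt1(x$aic), " concordance =", format(round(x$concordance, 2)), "\n")
  cat("  reference diagnosis:", x$reference_dx, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a registry Cox fit
#'
#' @param x A `glomreg_cox` object.
#' @param ... Unused.
#' @return Tibble with `term`, `hr`, `conf.low`, `conf.high`, `p.value`.
#'   The reference categories carry an implicit hazard ratio of 1 and are
#'   not reported.
#' @method tidy glomreg_cox
#' @export
tidy.glomreg_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hr = s$conf.int[, "exp(coef)"],
    conf.low = s$conf.int[, "lower .95"],
    conf.high = s$conf.int[, "upper .95"],
    p.value = s$coefficients[, "Pr(>|z|)"]
  )
}

#' One-row model summary for a registry Cox fit
#'
#' The concordance statistic is Harrell's C ("AUC" in published model
#' tables is reported as this global concordance index).
#'
#' @param x A `glomreg_cox` object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_event`, `aic`, `concordance`.
#' @method glance glomreg_cox
#' @export
glance.glomreg_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, aic = x$aic,
                 concordance = x$concordance)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot a Kaplan-Meier estimate
#'
#' @param object A `glomreg_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object (step survival curve with censoring marks).
#' @method autoplot glomreg_km
#' @export
autoplot.glomreg_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1),
    tibble::as_tibble(object)[, c("time", "surv")]
  )
  cens <- tibble::as_tibble(object)[object$n_censor > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since biopsy", y = "Survival probability") +
    ggplot2::theme_minimal()
  if (nrow(cens) > 0) {
    p <- p + ggplot2::geom_point(data = cens, shape = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of hazard ratios
#'
#' @param x A `glomreg_cox` object.
#' @return A ggplot object.
#' @export
plot_hazard_ratios <- function(x) {
  td <- tidy(x)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
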