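#' @importFrom rlang .data
NULL

# Per-diagnosis clinical profiles used to draw covariates. Means/medians for
# the eight common diagnoses follow the published descriptive table; other
# categories use field-plausible defaults (documented as arbitrary).
dx_profiles <- function() {
  prof <- tibble::tribble(
    ~dx, ~age_mean, ~age_sd, ~egfr_med, ~uacr_med,
    ~p_bp, ~p_acei, ~p_statin, ~p_rural, ~claims_lambda,
    "fsgs", 51.2, 17.3, 50.0, 386.9, 0.809, 0.765, 0.435, 0.377, 1.0,
    "secondary_fsgs", 51.1, 16.0, 35.5, 169.5, 0.717, 0.717, 0.394, 0.299, 1.0,
    "iga_nephropathy", 43.1, 15.5, 45.0, 166.8, 0.588, 0.687, 0.226, 0.385, 1.0,
    "infection_related_gn", 50.5, 15.5, 15.0, 272.0, 0.820, 0.270, 0.306, 0.595, 2.5,
    "lupus_nephritis", 38.3, 15.4, 65.0, 210.0, 0.538, 0.515, 0.136, 0.420, 1.2,
    "membranous_nephropathy", 56.1, 14.0, 80.0, 385.4, 0.754, 0.844, 0.603, 0.358, 1.0,
    "pauci_immune_gn", 60.7, 15.8, 19.0, 129.1, 0.665, 0.217, 0.187, 0.525, 1.5,
    "minimal_change_disease", 52.0, 17.6, 58.0, 509.8, 0.754, 0.492, 0.230, 0.295, 0.6
  )
  default <- tibble::tibble(
    dx = "default", age_mean = 55, age_sd = 16, egfr_med = 40, uacr_med = 200,
    p_bp = 0.6, p_acei = 0.4, p_statin = 0.3, p_rural = 0.4,
    claims_lambda = 1.3
  )
  dplyr::bind_rows(prof, default)
}

profile_for <- function(dx) {
  prof <- dx_profiles()
  idx <- match(dx, prof$dx)
  idx[is.na(idx)] <- match("default", prof$dx)
  prof[idx, ]
}

era_bounds <- function(study_window) {
  lo <- study_window[1]
  hi <- study_window[2]
  starts <- pmax(as.Date(c("2002-01-01", "2007-01-01", "2013-01-01")), lo)
  ends <- pmin(as.Date(c("2006-12-31", "2012-12-31", "2019-12-31")), hi)
  list(starts = starts, ends = ends)
}

runif_dates <- function(n, from, to) {
  # uniform dates in [from, to]; `from`/`to` vectors or scalars
  from <- as.integer(as.Date(from))
  to <- as.integer(as.Date(to))
  as.Date(from + floor(stats::runif(n) * (to - from + 1)), origin = "1970-01-01")
}

sample_exact <- function(idx, k) {
  if (k <= 0) return(integer(0))
  if (length(idx) < k) {
    rlang::abort("Not enough eligible records to satisfy a configured count",
                 class = "glomreg_config_error")
  }
  if (length(idx) == 1) return(idx) # sample() scalar gotcha
  sample(idx, k)
}

# --- episode table ---------------------------------------------------------

build_episodes <- function(cfg) {
  counts <- cfg$diagnosis_counts[cfg$diagnosis_counts > 0]
  dx <- rep(names(counts), counts)
  n <- length(dx)
  ep <- tibble::tibble(
    episode_id = seq_len(n),
    dx = dx,
    dual_pair = NA_integer_,
    dual_role = NA_character_
  )

  dd <- cfg$dual_dx_pairs
  if (nrow(dd) > 0) {
    for (i in seq_len(nrow(dd))) {
      f <- sample_exact(which(ep$dx == dd$first_dx[i] & is.na(ep$dual_pair)), 1)
      s <- sample_exact(which(ep$dx == dd$second_dx[i] & is.na(ep$dual_pair)), 1)
      ep$dual_pair[c(f, s)] <- i
      ep$dual_role[f] <- "first"
      ep$dual_role[s] <- "second"
    }
  }

  # patients: one per non-dual episode; dual pairs share one patient
  ep$patient_key <- NA_integer_
  key <- 0L
  for (i in seq_len(nrow(dd))) {
    key <- key + 1L
    ep$patient_key[which(ep$dual_pair == i)] <- key
  }
  free <- which(is.na(ep$patient_key))
  ep$patient_key[free] <- key + seq_along(free)

  # era assignment: quotas where configured, 18/30/52 split otherwise;
  # a dual patient's first episode takes an era-1 slot and the second an
  # era-3 slot so the two biopsy dates are ordered
  ep$era <- NA_integer_
  ep$era[!is.na(ep$dual_role) & ep$dual_role == "first"] <- 1L
  ep$era[!is.na(ep$dual_role) & ep$dual_role == "second"] <- 3L
  ec <- cfg$era_counts
  for (d in unique(ep$dx)) {
    rows <- which(ep$dx == d)
    quota <- ec$n[ec$dx == d][order(ec$era[ec$dx == d])]
    if (length(quota) == 3) {
      used <- tabulate(ep$era[rows], nbins = 3)
      quota <- quota - used
      if (any(quota < 0)) {
        rlang::abort(paste0("Era quota for '", d,
                            "' cannot absorb dual-diagnosis episodes"),
                     class = "glomreg_config_error")
      }
      open <- rows[is.na(ep$era[rows])]
      eras <- rep(1:3, quota)
      ep$era[open] <- if (length(open) > 1) sample(eras) else eras
    } else {
      open <- rows[is.na(ep$era[rows])]
      ep$era[open] <- sample(1:3, length(open), replace = TRUE,
                             prob = c(0.18, 0.30, 0.52))
    }
  }

  eb <- era_bounds(cfg$study_window)
  ep$biopsy_date <- runif_dates(n, eb$starts[ep$era], eb$ends[ep$era])
  # guard for custom configs without era-1/era-3 slots for dual pairs
  if (nrow(dd) > 0) {
    for (i in seq_len(nrow(dd))) {
      f <- which(ep$dual_pair == i & ep$dual_role == "first")
      s <- which(ep$dual_pair == i & ep$dual_role == "second")
      if (ep$biopsy_date[f] >= ep$biopsy_date[s]) {
        mid <- mean(as.integer(cfg$study_window))
        ep$biopsy_date[f] <- runif_dates(1, cfg$study_window[1], as.Date(floor(mid), origin = "1970-01-01"))
        ep$biopsy_date[s] <- runif_dates(1, as.Date(ceiling(mid) + 1, origin = "1970-01-01"), cfg$study_window[2])
      }
    }
  }

  # sex: exact female quotas per configured diagnosis, assigned patient-level
  # (a dual patient's sex is drawn from the first diagnosis and consumes the
  # quota of both of its categories)
  fq <- cfg$female_counts
  quota_left <- fq
  ep$sex <- NA_character_
  if (nrow(dd) > 0) {
    for (i in seq_len(nrow(dd))) {
      f <- which(ep$dual_pair == i & ep$dual_role == "first")
      s <- which(ep$dual_pair == i & ep$dual_role == "second")
      p <- if (dd$first_dx[i] %in% names(fq)) {
        fq[[dd$first_dx[i]]] / cfg$diagnosis_counts[[dd$first_dx[i]]]
      } else 0.45
      sx <- if (stats::runif(1) < p) "F" else "M"
      ep$sex[c(f, s)] <- sx
      if (sx == "F") {
        for (d in c(dd$first_dx[i], dd$second_dx[i])) {
          if (d %in% names(quota_left)) {
            quota_left[[d]] <- max(quota_left[[d]] - 1L, 0L)
          }
        }
      }
    }
  }
  for (d in unique(ep$dx)) {
    open <- which(ep$dx == d & is.na(ep$sex))
    if (d %in% names(quota_left)) {
      fem <- sample_exact(open, min(quota_left[[d]], length(open)))
      ep$sex[fem] <- "F"
      ep$sex[setdiff(open, fem)] <- "M"
    } else {
      ep$sex[open] <- ifelse(stats::runif(length(open)) < 0.45, "F", "M")
    }
  }

  # age and date of birth
  prof <- profile_for(ep$dx)
  age <- stats::rnorm(n, prof$age_mean, prof$age_sd)
  age <- pmin(pmax(age, 18), 90)
  ep$dob <- ep$biopsy_date - round(age * 365.25) - sample(0:300, n, replace = TRUE)
  ep
}

# --- multi-biopsy structure and linkage flags ------------------------------

flag_structure <- function(cfg, ep) {
  non_dual <- which(is.na(ep$dual_pair))
  start <- cfg$study_window[1]
  end <- cfg$study_window[2]

  elig_pre <- non_dual[ep$biopsy_date[non_dual] >= start + 180]
  pre <- sample_exact(elig_pre, cfg$n_nondx_before)

  elig_post <- setdiff(non_dual[ep$biopsy_date[non_dual] <= end - 180], pre)
  post <- sample_exact(elig_post, cfg$n_nondx_after)

  elig_rep <- setdiff(non_dual[ep$biopsy_date[non_dual] <= end - 180],
                      c(pre, post))
  reps <- sample_exact(elig_rep, cfg$n_repeat_same_dx)

  ep$has_nondx_pre <- seq_len(nrow(ep)) %in% pre
  ep$has_nondx_post <- seq_len(nrow(ep)) %in% post
  ep$has_repeat <- seq_len(nrow(ep)) %in% reps
  ep
}

assign_linkage_and_events <- function(cfg, ep) {
  # unlinked patients come from categories outside the two glomerulonephritis
  # broad groups, so neither the common-GN individual count nor the
  # post-linkage proliferative/nonproliferative biopsy totals are touched by
  # linkage failures
  grp <- broad_group(ep$dx)
  pool_keys <- unique(ep$patient_key[
    !(grp %in% c("proliferative_gn", "nonproliferative_gn"))
  ])
  n_from_ep <- min(cfg$n_unlinked, length(pool_keys))
  unlinked_keys <- sample_exact(pool_keys, n_from_ep)
  # remainder (if any) comes from nondiagnostic-only patients, handled later
  n_unlinked_nondx <- cfg$n_unlinked - n_from_ep
  ep$unlinked <- ep$patient_key %in% unlinked_keys

  # outcome events: exact counts per configured diagnosis among linked,
  # non-dual episodes; unconfigured categories draw events stochastically
  ep$kf <- FALSE
  ep$death <- FALSE
  oc <- cfg$outcome_counts
  for (d in unique(ep$dx)) {
    elig <- which(ep$dx == d & is.na(ep$dual_pair) & !ep$unlinked)
    row <- which(oc$dx == d)
    if (length(row) == 1) {
      ep$kf[sample_exact(elig, oc$kidney_failure[row])] <- TRUE
      ep$death[sample_exact(elig, oc$death[row])] <- TRUE
    } else {
      ep$kf[elig] <- stats::runif(length(elig)) < 0.35
      ep$death[elig] <- stats::runif(length(elig)) < 0.25
    }
  }

  # prevalent kidney-replacement therapy: dialysis before index; drawn from
  # diabetic nephropathy episodes without an incident event
  ep$prevalent_krt <- FALSE
  elig_prev <- which(ep$dx == "diabetic_nephropathy" & !ep$unlinked &
                       is.na(ep$dual_pair) & !ep$kf)
  ep$prevalent_krt[sample_exact(elig_prev, min(cfg$n_prevalent_krt, length(elig_prev)))] <- TRUE

  # event timing: within (index, follow_up_end]; dialysis precedes death
  n <- nrow(ep)
  span <- as.numeric(cfg$follow_up_end - ep$biopsy_date)
  f1 <- stats::runif(n, 0.08, 0.95)
  f2 <- stats::runif(n, 0.08, 0.95)
  both <- ep$kf & ep$death
  kf_frac <- ifelse(both, pmin(f1, f2), f1)
  death_frac <- ifelse(both, pmax(f1, f2) + 0.02, f2)
  ep$kf_date <- as.Date(ifelse(ep$kf, ep$biopsy_date + pmax(30, round(kf_frac * span)),
                               NA), origin = "1970-01-01")
  ep$death_date <- as.Date(ifelse(ep$death, ep$biopsy_date + pmax(45, round(pmin(death_frac, 0.98) * span)),
                                  NA), origin = "1970-01-01")
  ep$kf_date <- pmin(ep$kf_date, cfg$follow_up_end - 1, na.rm = FALSE)
  ep$death_date <- pmin(ep$death_date, cfg$follow_up_end, na.rm = FALSE)

  # early coverage loss for a handful of event-free linked patients
  ep$coverage_end <- as.Date(NA)
  elig_cl <- which(!ep$unlinked & is.na(ep$dual_pair) & !ep$kf & !ep$death &
                     !ep$prevalent_krt)
  cl <- sample_exact(elig_cl, min(cfg$n_coverage_loss, length(elig_cl)))
  ep$coverage_end[cl] <- ep$biopsy_date[cl] + sample(200:900, length(cl), replace = TRUE)
  ep$coverage_end[cl] <- pmin(ep$coverage_end[cl], cfg$follow_up_end - 30)

  list(episodes = ep, n_unlinked_nondx = n_unlinked_nondx)
}

# --- report-level ground truth ---------------------------------------------

if_antibodies <- function() c("IgG", "IgA", "IgM", "C3", "C1q", "kappa", "lambda")

draw_microscopy <- function(dx) {
  n <- length(dx)
  sclerosing <- dx %in% c("fsgs", "secondary_fsgs", "diabetic_nephropathy",
                          "ischemic_hypertensive")
  crescentic <- dx %in% c("pauci_immune_gn", "lupus_nephritis",
                          "iga_nephropathy", "infection_related_gn", "mpgn")
  total <- sample(10:35, n, replace = TRUE)
  global <- stats::rbinom(n, total, ifelse(sclerosing, 0.30, 0.12))
  segmental <- stats::rbinom(n, total - global, ifelse(sclerosing, 0.15, 0.05))
  crescents <- ifelse(crescentic & stats::runif(n) < 0.5,
                      sample(seq(5, 80, 5), n, replace = TRUE), 0L)
  ifta <- sample(c("none", "mild", "moderate", "severe"), n, replace = TRUE,
                 prob = c(0.30, 0.35, 0.25, 0.10))
  effacement <- ifelse(dx %in% c("minimal_change_disease", "fsgs",
                                 "membranous_nephropathy"),
                       sample(60:100, n, replace = TRUE),
                       sample(0:40, n, replace = TRUE))
  out <- tibble::tibble(
    glomeruli_total = as.integer(total),
    glomeruli_global_sclerosis = as.integer(global),
    glomeruli_segmental_sclerosis = as.integer(segmental),
    crescents_pct = as.integer(crescents),
    ifta_grade = ifta,
    em_effacement_pct = as.integer(effacement)
  )
  # immunofluorescence panel: broad diagnosis-driven tilts
  base <- matrix(sample(0:1, n * 7, replace = TRUE, prob = c(0.7, 0.3)),
                 nrow = n)
  colnames(base) <- paste0("if_", tolower(if_antibodies()))
  base[dx == "iga_nephropathy", "if_iga"] <- sample(2:3, sum(dx == "iga_nephropathy"), replace = TRUE)
  base[dx == "membranous_nephropathy", "if_igg"] <- sample(2:3, sum(dx == "membranous_nephropathy"), replace = TRUE)
  lup <- dx == "lupus_nephritis"
  if (any(lup)) {
    for (ab in c("if_igg", "if_iga", "if_igm", "if_c3", "if_c1q")) {
      base[lup, ab] <- sample(1:3, sum(lup), replace = TRUE)
    }
  }
  dplyr::bind_cols(out, tibble::as_tibble(base))
}

empty_microscopy <- function(n) {
  out <- tibble::tibble(
    glomeruli_total = sample(0:2, n, replace = TRUE),
    glomeruli_global_sclerosis = NA_integer_,
    glomeruli_segmental_sclerosis = NA_integer_,
    crescents_pct = NA_integer_,
    ifta_grade = NA_character_,
    em_effacement_pct = NA_integer_
  )
  for (ab in paste0("if_", tolower(if_antibodies()))) out[[ab]] <- NA_integer_
  out
}

add_scores <- function(rep) {
  n <- nrow(rep)
  iga <- !is.na(rep$primary_dx) & rep$primary_dx == "iga_nephropathy"
  rep$oxford_m <- ifelse(iga, stats::rbinom(n, 1, 0.6), NA_integer_)
  rep$oxford_e <- ifelse(iga, stats::rbinom(n, 1, 0.3), NA_integer_)
  rep$oxford_s <- ifelse(iga, stats::rbinom(n, 1, 0.5), NA_integer_)
  rep$oxford_t <- ifelse(iga, sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)), NA_integer_)
  rep$oxford_c <- ifelse(iga, sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)), NA_integer_)
  lup <- !is.na(rep$primary_dx) & rep$primary_dx == "lupus_nephritis"
  rep$ln_activity <- ifelse(lup, sample(0:24, n, replace = TRUE), NA_integer_)
  rep$ln_chronicity <- ifelse(lup, sample(0:12, n, replace = TRUE), NA_integer_)
  rep
}

build_reports <- function(cfg, ep, n_unlinked_nondx) {
  mk <- function(patient_key, dx, secondary, date, dob, sex, role, episode_id) {
    tibble::tibble(
      patient_key = patient_key, primary_dx = dx, secondary_dx = secondary,
      biopsy_date = date, dob = dob, sex = sex, role = role,
      episode_id = episode_id, diagnostic = !startsWith(role, "nondx")
    )
  }

  end <- cfg$study_window[2]
  start <- cfg$study_window[1]

  # secondary diagnoses: an acute process on a chronic background
  sec <- rep(NA_character_, nrow(ep))
  acute <- which(ep$dx %in% c("infection_related_gn", "pauci_immune_gn",
                              "acute_tubular_injury"))
  pick <- acute[stats::runif(length(acute)) < 0.10]
  sec[pick] <- sample(c("diabetic_nephropathy", "ischemic_hypertensive"),
                      length(pick), replace = TRUE)

  index <- mk(ep$patient_key, ep$dx, sec, ep$biopsy_date, ep$dob, ep$sex,
              "index", ep$episode_id)

  pieces <- list(index)

  r <- which(ep$has_repeat)
  if (length(r) > 0) {
    gap <- sample(120:1095, length(r), replace = TRUE)
    d <- pmin(ep$biopsy_date[r] + gap, end)
    pieces <- c(pieces, list(
      mk(ep$patient_key[r], ep$dx[r], NA_character_, d, ep$dob[r], ep$sex[r],
         "repeat", ep$episode_id[r])
    ))
  }

  p <- which(ep$has_nondx_pre)
  if (length(p) > 0) {
    back <- sample(60:1095, length(p), replace = TRUE)
    d <- pmax(ep$biopsy_date[p] - back, start)
    pieces <- c(pieces, list(
      mk(ep$patient_key[p], NA_character_, NA_character_, d, ep$dob[p],
         ep$sex[p], "nondx_pre", ep$episode_id[p])
    ))
  }

  q <- which(ep$has_nondx_post)
  if (length(q) > 0) {
    fwd <- sample(60:1095, length(q), replace = TRUE)
    d <- pmin(ep$biopsy_date[q] + fwd, end)
    pieces <- c(pieces, list(
      mk(ep$patient_key[q], NA_character_, NA_character_, d, ep$dob[q],
         ep$sex[q], "nondx_post", ep$episode_id[q])
    ))
  }

  if (cfg$n_nondx_only > 0) {
    n0 <- cfg$n_nondx_only
    key0 <- max(ep$patient_key) + seq_len(n0)
    d <- runif_dates(n0, start, end)
    age <- pmin(pmax(stats::rnorm(n0, 55, 16), 18), 90)
    pieces <- c(pieces, list(
      mk(key0, NA_character_, NA_character_, d,
         d - round(age * 365.25) - sample(0:300, n0, replace = TRUE),
         ifelse(stats::runif(n0) < 0.5, "F", "M"), "nondx_only", NA_integer_)
    ))
  }

  rep_tbl <- dplyr::bind_rows(pieces)

  # microscopy ground truth
  diag <- rep_tbl$diagnostic
  micro <- empty_microscopy(nrow(rep_tbl))
  if (any(diag)) micro[diag, ] <- draw_microscopy(rep_tbl$primary_dx[diag])
  rep_tbl <- dplyr::bind_cols(rep_tbl, micro)
  rep_tbl <- add_scores(rep_tbl)

  # nondiagnostic-only patients can also fail linkage
  if (n_unlinked_nondx > 0) {
    keys <- unique(rep_tbl$patient_key[rep_tbl$role == "nondx_only"])
    extra <- sample_exact(keys, n_unlinked_nondx)
    attr(rep_tbl, "extra_unlinked_keys") <- extra
  }

  # stable document identifiers in chronological order
  ord <- order(rep_tbl$biopsy_date, rep_tbl$patient_key)
  rep_tbl <- rep_tbl[ord, ]
  rep_tbl$doc_id <- sprintf("BX%06d", seq_len(nrow(rep_tbl)))
  dplyr::relocate(rep_tbl, "doc_id")
}

# --- administrative bundle --------------------------------------------------

default_atc_codes <- function() {
  list(
    acei_arb = c("C09AA02", "C09AA05", "C09CA01", "C09CA06"),
    statin = c("C10AA01", "C10AA05", "C10AA07"),
    antihypertensive_non_raasi = c("C03CA01", "C07AB02", "C08CA01", "C02AC01")
  )
}

ses_profile <- function(dx) {
  tab <- list(
    fsgs = c(29, 21, 15, 27, 22),
    secondary_fsgs = c(31, 26, 33, 21, 16),
    iga_nephropathy = c(118, 75, 66, 76, 36),
    infection_related_gn = c(56, 25, 10, 12, 8),
    lupus_nephritis = c(35, 27, 21, 29, 19),
    membranous_nephropathy = c(44, 38, 22, 40, 35),
    pauci_immune_gn = c(55, 41, 31, 40, 35),
    minimal_change_disease = c(15, 12, 9, 8, 17)
  )
  lapply(dx, function(d) {
    w <- tab[[d]]
    if (is.null(w)) w <- c(1, 1, 1, 1, 1)
    w / sum(w)
  })
}

build_admin <- function(cfg, ep, rep_tbl, phin_map) {
  extra_unlinked <- attr(rep_tbl, "extra_unlinked_keys")
  unlinked_keys <- unique(c(ep$patient_key[ep$unlinked], extra_unlinked))

  patients <- rep_tbl |>
    dplyr::distinct(.data$patient_key, .keep_all = TRUE) |>
    dplyr::select("patient_key", "dob")
  patients$linked <- !(patients$patient_key %in% unlinked_keys)
  patients$patient_id <- phin_map[as.character(patients$patient_key)]

  # coverage: linked patients covered from well before the study window to
  # past study end, except the configured early-coverage-loss episodes
  cov <- patients[patients$linked, ]
  cov_end <- rep(as.Date("2021-12-31"), nrow(cov))
  loss <- ep[!is.na(ep$coverage_end), c("patient_key", "coverage_end")]
  idx <- match(cov$patient_key, loss$patient_key)
  cov_end[!is.na(idx)] <- loss$coverage_end[idx[!is.na(idx)]]
  coverage <- tibble::tibble(
    patient_id = cov$patient_id,
    start_date = as.Date("1992-01-01"),
    end_date = cov_end
  )

  # helper: linked index episodes with identifiers
  epl <- ep[!ep$unlinked, ]
  epl$patient_id <- phin_map[as.character(epl$patient_key)]
  prof <- profile_for(epl$dx)
  n <- nrow(epl)

  # labs: one eGFR and one uACR/uPCR inside the +/-3-month window per
  # episode, plus decoys outside the window
  egfr_val <- round(stats::rlnorm(n, log(prof$egfr_med), 0.5), 0)
  uacr_val <- round(stats::rlnorm(n, log(prof$uacr_med), 0.8), 1)
  upcr <- stats::runif(n) < 0.2
  labs <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = epl$patient_id, test = "eGFR", value = egfr_val,
      units = "mL/min/1.73m2",
      date = epl$biopsy_date + sample(-85:85, n, replace = TRUE)
    ),
    tibble::tibble(
      patient_id = epl$patient_id,
      test = ifelse(upcr, "uPCR", "uACR"),
      value = uacr_val, units = "mg/mmol",
      date = epl$biopsy_date + sample(-85:85, n, replace = TRUE)
    )
  )
  decoy <- stats::runif(n) < 0.3
  if (any(decoy)) {
    labs <- dplyr::bind_rows(labs, tibble::tibble(
      patient_id = epl$patient_id[decoy], test = "eGFR",
      value = round(egfr_val[decoy] * stats::runif(sum(decoy), 0.6, 1.6), 0),
      units = "mL/min/1.73m2",
      date = epl$biopsy_date[decoy] - sample(200:400, sum(decoy), replace = TRUE)
    ))
  }

  # drug dispensations within 6 months post-biopsy
  atc <- default_atc_codes()
  disp <- list()
  for (class in names(atc)) {
    p <- switch(class,
      acei_arb = prof$p_acei,
      statin = prof$p_statin,
      antihypertensive_non_raasi = prof$p_bp
    )
    hit <- stats::runif(n) < p
    disp[[class]] <- tibble::tibble(
      patient_id = epl$patient_id[hit],
      atc_code = sample(atc[[class]], sum(hit), replace = TRUE),
      date = epl$biopsy_date[hit] + sample(5:170, sum(hit), replace = TRUE)
    )
  }
  dispensations <- dplyr::bind_rows(disp)

  # diagnostic claims feeding the comorbidity index (3-year lookback),
  # plus out-of-window decoys that must not be counted
  conds <- names(charlson_weights())
  n_claims <- pmin(stats::rpois(n, prof$claims_lambda), length(conds))
  claims <- tibble::tibble(
    patient_id = rep(epl$patient_id, n_claims),
    condition_code = unlist(lapply(n_claims, function(k) {
      sample(conds, k, prob = c(rep(3, 10), rep(1, length(conds) - 10)))
    })),
    date = rep(epl$biopsy_date, n_claims) -
      sample(30:1000, sum(n_claims), replace = TRUE)
  )
  old <- stats::runif(n) < 0.2
  claims <- dplyr::bind_rows(claims, tibble::tibble(
    patient_id = epl$patient_id[old],
    condition_code = sample(conds, sum(old), replace = TRUE),
    date = epl$biopsy_date[old] - sample(1200:1460, sum(old), replace = TRUE)
  ))

  deaths <- tibble::tibble(
    patient_id = epl$patient_id[epl$death],
    death_date = epl$death_date[epl$death]
  )

  krt_events <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = epl$patient_id[epl$kf],
      event = ifelse(stats::runif(sum(epl$kf)) < 0.8, "dialysis_start", "transplant"),
      date = epl$kf_date[epl$kf]
    ),
    tibble::tibble(
      patient_id = epl$patient_id[epl$prevalent_krt],
      event = "dialysis_start",
      date = epl$biopsy_date[epl$prevalent_krt] -
        sample(180:720, sum(epl$prevalent_krt), replace = TRUE)
    )
  )

  # census: one row per linked patient, drawn from the profile of the
  # patient's first episode (nondiagnostic-only patients use defaults)
  first_ep <- epl[!duplicated(epl$patient_key), ]
  census_keys <- patients$patient_key[patients$linked]
  cidx <- match(census_keys, first_ep$patient_key)
  cdx <- ifelse(is.na(cidx), "default", first_ep$dx[cidx])
  ses_w <- ses_profile(cdx)
  cprof <- profile_for(cdx)
  census <- tibble::tibble(
    patient_id = patients$patient_id[patients$linked],
    ses_quintile = vapply(ses_w, function(w) sample(1:5, 1, prob = w), 1L),
    dwelling = ifelse(stats::runif(length(census_keys)) < cprof$p_rural,
                      "rural", "urban")
  )

  list(
    coverage = coverage, labs = labs, dispensations = dispensations,
    claims = claims, deaths = deaths, krt_events = krt_events, census = census
  )
}

# --- top level --------------------------------------------------------------

#' Generate the synthetic registry universe
#'
#' Draws the full fixture: ground-truth biopsy records (one row per report
#' document), per-document rendering styles, and the companion administrative
#' bundle. Per-diagnosis episode counts, outcome event counts, female quotas
#' and era quotas are reproduced exactly; everything else is drawn from
#' seeded distributions. Identical `(config, seed)` yields identical output.
#'
#' @param config A [registry_config()].
#' @return A list with elements `truth` (tibble, one row per report),
#'   `styles` (tibble of per-document style profiles), `admin` (list of
#'   administrative tibbles: coverage, labs, dispensations, claims, deaths,
#'   krt_events, census), and `config`.
#' @export
generate_registry <- function(config = registry_config()) {
  validate_registry_config(config)
  withr::with_seed(config$seed, {
    if (sum(config$diagnosis_counts) == 0 && config$n_nondx_only == 0) {
      return(empty_registry(config))
    }
    ep <- build_episodes(config)
    ep <- flag_structure(config, ep)
    lk <- assign_linkage_and_events(config, ep)
    ep <- lk$episodes
    rep_tbl <- build_reports(config, ep, lk$n_unlinked_nondx)

    # 9-digit synthetic health identifiers, patient-level
    keys <- sort(unique(rep_tbl$patient_key))
    phin <- sprintf("%09d", sample.int(899999999L, length(keys)) + 100000000L)
    phin_map <- stats::setNames(phin, as.character(keys))
    rep_tbl$patient_id <- phin_map[as.character(rep_tbl$patient_key)]

    admin <- build_admin(config, ep, rep_tbl, phin_map)
    styles <- sample_styles(config, rep_tbl)
    truth <- apply_style_drops(rep_tbl, styles)
    list(truth = truth, styles = styles, admin = admin, config = config)
  })
}

truth_schema <- function() {
  out <- tibble::tibble(
    doc_id = character(), patient_key = integer(), primary_dx = character(),
    secondary_dx = character(), biopsy_date = as.Date(character()),
    dob = as.Date(character()), sex = character(), role = character(),
    episode_id = integer(), diagnostic = logical(),
    glomeruli_total = integer(), glomeruli_global_sclerosis = integer(),
    glomeruli_segmental_sclerosis = integer(), crescents_pct = integer(),
    ifta_grade = character(), em_effacement_pct = integer()
  )
  for (ab in paste0("if_", tolower(if_antibodies()))) out[[ab]] <- integer()
  out$oxford_m <- integer(); out$oxford_e <- integer()
  out$oxford_s <- integer(); out$oxford_t <- integer(); out$oxford_c <- integer()
  out$ln_activity <- integer(); out$ln_chronicity <- integer()
  out$patient_id <- character()
  out
}

empty_registry <- function(config) {
  truth <- truth_schema()
  empty_admin <- list(
    coverage = tibble::tibble(patient_id = character(), start_date = as.Date(character()), end_date = as.Date(character())),
    labs = tibble::tibble(patient_id = character(), test = character(), value = numeric(), units = character(), date = as.Date(character())),
    dispensations = tibble::tibble(patient_id = character(), atc_code = character(), date = as.Date(character())),
    claims = tibble::tibble(patient_id = character(), condition_code = character(), date = as.Date(character())),
    deaths = tibble::tibble(patient_id = character(), death_date = as.Date(character())),
    krt_events = tibble::tibble(patient_id = character(), event = character(), date = as.Date(character())),
    census = tibble::tibble(patient_id = character(), ses_quintile = integer(), dwelling = character())
  )
  list(truth = truth, styles = sample_styles(config, truth),
       admin = empty_admin, config = config)
}
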