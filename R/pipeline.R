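#' Write a fixture corpus to disk
#'
#' Lays out the corpus as plain text and CSV: one `reports/<doc_id>.txt`
#' file per document, the administrative tables under `admin/`, and the
#' ground-truth manifest as `manifest.csv`. Re-running with the same inputs
#' yields byte-identical files.
#'
#' @param documents Tibble from [render_reports()].
#' @param truth Ground-truth tibble from [generate_registry()].
#' @param admin Administrative bundle from [generate_registry()].
#' @param out_dir Output directory (created if needed).
#' @return Tibble of written files with MD5 checksums.
#' @export
write_fixture_corpus <- function(documents, truth, admin, out_dir) {
  rep_dir <- file.path(out_dir, "reports")
  adm_dir <- file.path(out_dir, "admin")
  ok <- dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(adm_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(rep_dir) || !dir.exists(adm_dir)) {
    rlang::abort(paste0("Cannot create corpus directory: ", out_dir),
                 class = "glomreg_io_error")
  }
  for (i in seq_len(nrow(documents))) {
    writeLines(documents$text[i],
               file.path(rep_dir, paste0(documents$doc_id[i], ".txt")))
  }
  write_csv_plain(truth, file.path(out_dir, "manifest.csv"))
  admin_names <- c(coverage = "coverage", labs = "labs",
                   dispensations = "dispensations", claims = "claims",
                   deaths = "deaths", krt_events = "krt", census = "census")
  for (nm in names(admin_names)) {
    write_csv_plain(admin[[nm]], file.path(adm_dir, paste0(admin_names[[nm]], ".csv")))
  }
  files <- c(
    file.path(rep_dir, paste0(documents$doc_id, ".txt")),
    file.path(out_dir, "manifest.csv"),
    file.path(adm_dir, paste0(admin_names, ".csv"))
  )
  tibble::tibble(file = files, md5 = unname(tools::md5sum(files)))
}

write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

read_csv_plain <- function(path, date_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  out <- tibble::as_tibble(df)
  for (cl in date_cols) if (cl %in% names(out)) out[[cl]] <- as.Date(out[[cl]])
  out
}

#' Read a fixture corpus from disk
#'
#' Inverse of [write_fixture_corpus()].
#'
#' @param dir Corpus directory.
#' @return List with `documents`, `truth`, `admin`.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(file.path(dir, "reports"), pattern = "\\.txt$",
                           full.names = TRUE))
  documents <- tibble::tibble(
    doc_id = sub("\\.txt$", "", basename(files)),
    text = vapply(files, function(f) paste(readLines(f), collapse = "\n"),
                  character(1), USE.NAMES = FALSE)
  )
  truth <- read_csv_plain(file.path(dir, "manifest.csv"),
                          date_cols = c("biopsy_date", "dob"))
  num_cols <- setdiff(names(truth_schema())[vapply(truth_schema(), is.numeric, TRUE)],
                      character(0))
  for (cl in intersect(num_cols, names(truth))) {
    truth[[cl]] <- as.integer(truth[[cl]])
  }
  if ("diagnostic" %in% names(truth)) {
    truth$diagnostic <- truth$diagnostic == "TRUE"
  }
  adm <- file.path(dir, "admin")
  admin <- list(
    coverage = read_csv_plain(file.path(adm, "coverage.csv"),
                              c("start_date", "end_date")),
    labs = read_csv_plain(file.path(adm, "labs.csv"), "date"),
    dispensations = read_csv_plain(file.path(adm, "dispensations.csv"), "date"),
    claims = read_csv_plain(file.path(adm, "claims.csv"), "date"),
    deaths = read_csv_plain(file.path(adm, "deaths.csv"), "death_date"),
    krt_events = read_csv_plain(file.path(adm, "krt.csv"), "date"),
    census = read_csv_plain(file.path(adm, "census.csv"))
  )
  admin$labs$value <- as.numeric(admin$labs$value)
  admin$census$ses_quintile <- as.integer(admin$census$ses_quintile)
  list(documents = documents, truth = truth, admin = admin)
}

#' Run the full registry pipeline
#'
#' Orchestrates generate -> render -> parse -> classify -> link/build ->
#' analyze -> audit as one seeded, reproducible run, returning every stage
#' artifact plus a run manifest (stage timings, content hashes, headline
#' counts). All randomness flows from the config's root seed.
#'
#' @param config A [registry_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as CSV (and the corpus as text files).
#' @param audit_n,audit_min_per_year Audit sample parameters; the audit is
#'   skipped (with a manifest warning) when the corpus cannot satisfy them.
#' @param fit_models Fit the two Cox models? (Requires enough events.)
#' @return List of class `glomreg_run`: `truth`, `documents`, `parsed`,
#'   `classified`, `cohort`, `table1`, `audit`, `cox` and `manifest`.
#' @export
run_registry_pipeline <- function(config = registry_config(), out_dir = NULL,
                                  audit_n = 100, audit_min_per_year = 5,
                                  fit_models = TRUE) {
  manifest <- list(seed = config$seed, timings = list(), warnings = character())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  gen <- generate_registry(config)
  documents <- render_reports(gen$truth, gen$styles)
  manifest$timings$generate <- tic() - t0

  t1 <- tic()
  parsed <- parse_reports(documents)
  classified <- classify_reports(parsed)
  manifest$timings$parse <- tic() - t1

  t2 <- tic()
  cohort <- build_cohort(classified, gen$admin,
                         follow_up_end = config$follow_up_end)
  manifest$timings$cohort <- tic() - t2

  t3 <- tic()
  table1 <- descriptive_table(cohort)
  audit <- NULL
  audit_feasible <- nrow(gen$truth) >= audit_n
  if (audit_feasible) {
    audit <- tryCatch(
      score_extraction(
        classified, gen$truth,
        doc_ids = sample_audit_set(gen$truth, audit_n, audit_min_per_year,
                                   seed = config$seed + 1L)
      ),
      glomreg_audit_error = function(e) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(e))
        NULL
      }
    )
  }
  cox <- NULL
  if (fit_models && nrow(cohort) > 0) {
    cox <- list(
      kidney_failure = tryCatch(cox_fit(cohort, "kidney_failure"),
                                error = function(e) NULL),
      mortality = tryCatch(cox_fit(cohort, "mortality"),
                           error = function(e) NULL)
    )
  }
  manifest$timings$analyze <- tic() - t3

  linkage <- attr(cohort, "linkage")
  manifest$counts <- list(
    n_reports = nrow(gen$truth),
    n_patients = dplyr::n_distinct(gen$truth$patient_id),
    n_nondiagnostic = sum(parsed$parse_status == "nondiagnostic"),
    n_linked_individuals = linkage$n_linked_individuals,
    n_unlinked_individuals = linkage$n_unlinked_individuals,
    n_common_gn_individuals = dplyr::n_distinct(
      cohort$patient_id[cohort$common_gn]
    ),
    n_index_episodes = nrow(cohort)
  )
  manifest$hashes <- list(
    truth = rlang::hash(gen$truth),
    documents = rlang::hash(documents),
    parsed = rlang::hash(dplyr::as_tibble(parsed)),
    cohort = rlang::hash(cohort)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixture_corpus(documents, gen$truth, gen$admin,
                         file.path(out_dir, "corpus"))
    write_csv_plain(classified, file.path(out_dir, "classified.csv"))
    write_csv_plain(cohort, file.path(out_dir, "cohort.csv"))
    write_csv_plain(table1, file.path(out_dir, "table1.csv"))
    if (!is.null(audit)) {
      jsonlite::write_json(
        list(field_accuracy = audit$field_accuracy,
             overall_accuracy = audit$overall_accuracy,
             discrepancies = audit$discrepancies),
        file.path(out_dir, "audit.json"), auto_unbox = TRUE, digits = NA
      )
    }
    manifest_out <- manifest
    jsonlite::write_json(manifest_out, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(
      truth = gen$truth, styles = gen$styles, admin = gen$admin,
      documents = documents, parsed = parsed, classified = classified,
      cohort = cohort, table1 = table1, audit = audit, cox = cox,
      manifest = manifest
    ),
    class = "glomreg_run"
  )
}

#' @export
print.glomreg_run <- function(x, ...) {
  cat("<glomreg_run>\n")
  cts <- x$manifest$counts
  for (nm in names(cts)) cat("  ", nm, ": ", cts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [registry_config()] (counts as
#' maps, dates as strings); omitted keys keep their defaults.
#'
#' @param path Path to a YAML configuration.
#' @return A [registry_config()].
#' @export
read_registry_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  if (!is.null(y$diagnosis_counts)) {
    args$diagnosis_counts <- unlist(y$diagnosis_counts)
    # the packaged outcome/female/era/dual quotas describe the default
    # composition; a custom composition starts from empty quotas unless the
    # file provides its own
    args$outcome_counts <- default_outcome_counts()[0, ]
    args$female_counts <- stats::setNames(
      integer(0), character(0)
    )
    args$era_counts <- default_era_counts()[0, ]
    args$dual_dx_pairs <- default_dual_dx_pairs()[0, ]
  }
  if (!is.null(y$outcome_counts)) {
    oc <- y$outcome_counts
    args$outcome_counts <- tibble::tibble(
      dx = names(oc),
      kidney_failure = vapply(oc, function(x) as.integer(x$kidney_failure), 1L),
      death = vapply(oc, function(x) as.integer(x$death), 1L)
    )
  }
  if (!is.null(y$female_counts)) args$female_counts <- unlist(y$female_counts)
  if (!is.null(y$study_window)) args$study_window <- as.Date(unlist(y$study_window))
  if (!is.null(y$follow_up_end)) args$follow_up_end <- as.Date(y$follow_up_end)
  for (nm in c("n_repeat_same_dx", "n_nondx_before", "n_nondx_after",
               "n_nondx_only", "n_unlinked", "n_coverage_loss",
               "n_prevalent_krt")) {
    if (!is.null(y[[nm]])) args[[nm]] <- as.integer(y[[nm]])
  }
  if (!is.null(y$style)) args$style <- do.call(style_config, y$style)
  do.call(registry_config, args)
}
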