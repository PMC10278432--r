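#' Fields compared by the extraction audit
#' @return Character vector of field names.
#' @export
audit_fields <- function() {
  c(
    "patient_id", "biopsy_date", "dob", "sex", "diagnostic",
    "primary_dx", "secondary_dx",
    "glomeruli_total", "glomeruli_global_sclerosis",
    "glomeruli_segmental_sclerosis", "crescents_pct", "ifta_grade",
    paste0("if_", tolower(if_antibodies())), "em_effacement_pct",
    paste0("oxford_", c("m", "e", "s", "t", "c")),
    "ln_activity", "ln_chronicity"
  )
}

#' Draw a stratified random audit sample
#'
#' Samples `n` document ids with at least `min_per_year` from every calendar
#' year that has biopsies: the per-year minimum is drawn first, then the
#' remainder at random from the rest. Deterministic under `seed`.
#'
#' @param manifest Ground-truth manifest (needs `doc_id`, `biopsy_date`).
#' @param n Total sample size.
#' @param min_per_year Minimum documents per calendar year.
#' @param seed Integer seed.
#' @return Character vector of `n` document ids.
#' @export
sample_audit_set <- function(manifest, n = 100, min_per_year = 5,
                             seed = 1L) {
  if (n > nrow(manifest)) {
    rlang::abort("Audit sample size exceeds the corpus",
                 class = "glomreg_audit_error")
  }
  yr <- lubridate::year(manifest$biopsy_date)
  tab <- table(yr)
  deficient <- names(tab)[tab < min_per_year]
  if (length(deficient) > 0) {
    rlang::abort(
      paste0("Years with fewer than ", min_per_year, " biopsies: ",
             paste(deficient, collapse = ", ")),
      class = "glomreg_audit_error"
    )
  }
  if (n < min_per_year * length(tab)) {
    rlang::abort(
      paste0("n = ", n, " cannot satisfy ", min_per_year, " per year over ",
             length(tab), " years"),
      class = "glomreg_audit_error"
    )
  }
  withr::with_seed(seed, {
    base <- unlist(lapply(names(tab), function(y) {
      ids <- manifest$doc_id[yr == as.integer(y)]
      if (length(ids) == 1) ids else sample(ids, min_per_year)
    }))
    rest <- setdiff(manifest$doc_id, base)
    extra_n <- n - length(base)
    extra <- if (extra_n > 0) sample(rest, extra_n) else character(0)
    sort(c(base, extra))
  })
}

#' Score parser output against ground truth
#'
#' Exact-match comparison per field per document: a missing value where the
#' truth has one counts as an error, as does any conflict; two missing
#' values agree. Both per-field and per-document aggregations are reported.
#'
#' @param parsed Classified parse tibble ([classify_reports()]).
#' @param manifest Ground-truth manifest from [generate_registry()].
#' @param doc_ids Optional subset of documents to score (e.g. an audit
#'   sample); default scores every manifest document present in `parsed`.
#' @param fields Fields to compare.
#' @return List of class `glomreg_audit`: `field_accuracy` (tibble),
#'   `doc_accuracy`, `discrepancies`, `sample_composition` (per year),
#'   `overall_accuracy`.
#' @export
score_extraction <- function(parsed, manifest, doc_ids = NULL,
                             fields = audit_fields()) {
  if (is.null(doc_ids)) doc_ids <- intersect(manifest$doc_id, parsed$doc_id)
  truth <- manifest[match(doc_ids, manifest$doc_id), ]
  got <- parsed[match(doc_ids, parsed$doc_id), ]
  n <- length(doc_ids)
  if (n == 0) {
    return(structure(
      list(
        field_accuracy = tibble::tibble(field = fields, n = 0L,
                                        n_correct = 0L, accuracy = NA_real_),
        doc_accuracy = tibble::tibble(doc_id = character(), accuracy = numeric()),
        discrepancies = tibble::tibble(doc_id = character(), field = character(),
                                       truth = character(), parsed = character()),
        sample_composition = tibble::tibble(year = integer(), n = integer()),
        overall_accuracy = NA_real_
      ),
      class = "glomreg_audit"
    ))
  }
  fields <- intersect(fields, intersect(names(truth), names(got)))
  agree <- matrix(NA, n, length(fields), dimnames = list(NULL, fields))
  disc <- list()
  for (f in fields) {
    tv <- truth[[f]]
    pv <- got[[f]]
    same <- (is.na(tv) & is.na(pv)) |
      (!is.na(tv) & !is.na(pv) & as.character(tv) == as.character(pv))
    agree[, f] <- same
    if (any(!same)) {
      disc[[f]] <- tibble::tibble(
        doc_id = doc_ids[!same], field = f,
        truth = as.character(tv[!same]), parsed = as.character(pv[!same])
      )
    }
  }
  structure(
    list(
      field_accuracy = tibble::tibble(
        field = fields, n = n,
        n_correct = colSums(agree),
        accuracy = colSums(agree) / n
      ),
      doc_accuracy = tibble::tibble(
        doc_id = doc_ids, accuracy = rowMeans(agree)
      ),
      discrepancies = if (length(disc) > 0) dplyr::bind_rows(disc) else
        tibble::tibble(doc_id = character(), field = character(),
                       truth = character(), parsed = character()),
      sample_composition = truth |>
        dplyr::count(year = lubridate::year(.data$biopsy_date)),
      overall_accuracy = mean(agree)
    ),
    class = "glomreg_audit"
  )
}

#' @export
print.glomreg_audit <- function(x, ...) {
  cat("<glomreg_audit> documents:", nrow(x$doc_accuracy),
      " overall accuracy:", format(x$overall_accuracy, digits = 4), "\n")
  worst <- x$field_accuracy[order(x$field_accuracy$accuracy), ]
  print(utils::head(worst, 5))
  if (nrow(x$discrepancies) > 0) {
    cat("discrepancies:", nrow(x$discrepancies), "\n")
  }
  invisible(x)
}

#' Run the iterative development protocol
#'
#' Scores the parser on successive disjoint random samples of the configured
#' sizes (default 10, 20, 50 documents), emitting an accuracy trace per
#' stage for pattern-library tuning.
#'
#' @param parsed Classified parse tibble.
#' @param manifest Ground-truth manifest.
#' @param stage_sizes Integer vector of stage sample sizes.
#' @param seed Integer seed.
#' @return Tibble: `stage`, `size`, `overall_accuracy`,
#'   `min_field_accuracy`, `n_discrepancies`.
#' @export
iterative_protocol <- function(parsed, manifest, stage_sizes = c(10, 20, 50),
                               seed = 1L) {
  if (any(stage_sizes < 1)) {
    rlang::abort("Stage sizes must be positive", class = "glomreg_audit_error")
  }
  if (sum(stage_sizes) > nrow(manifest)) {
    rlang::abort("Stage sizes exceed the corpus",
                 class = "glomreg_audit_error")
  }
  withr::with_seed(seed, {
    pool <- manifest$doc_id
    purrr::map_dfr(seq_along(stage_sizes), function(k) {
      ids <- sample(pool, stage_sizes[k])
      pool <<- setdiff(pool, ids)
      sc <- score_extraction(parsed, manifest, doc_ids = ids)
      tibble::tibble(
        stage = k, size = stage_sizes[k],
        overall_accuracy = sc$overall_accuracy,
        min_field_accuracy = min(sc$field_accuracy$accuracy),
        n_discrepancies = nrow(sc$discrepancies)
      )
    })
  })
}
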