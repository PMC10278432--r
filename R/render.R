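the_cache <- new.env(parent = emptyenv())

#' Load the report template inventory
#'
#' Sentence templates live in a YAML file so new phrasing variants can be
#' added without code changes; each field has at least three variants,
#' including a number-word form for count-valued fields.
#'
#' @param path Path to a template YAML; `NULL` for the packaged default.
#' @return Nested list of per-field template vectors.
#' @export
default_templates <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_cache$templates)) return(the_cache$templates)
    path <- system.file("extdata", "report_templates.yaml", package = "glomreg")
    the_cache$templates <- yaml::read_yaml(path)
    return(the_cache$templates)
  }
  yaml::read_yaml(path)
}

canonical_section_order <- function() {
  c("patient_information", "gross_description", "microscopic_description",
    "immunofluorescence", "electron_microscopy", "diagnosis")
}

section_headers <- function(micro_header = "MICROSCOPIC DESCRIPTION") {
  c(
    patient_information = "PATIENT INFORMATION",
    gross_description = "GROSS DESCRIPTION",
    microscopic_description = micro_header,
    immunofluorescence = "IMMUNOFLUORESCENCE",
    electron_microscopy = "ELECTRON MICROSCOPY",
    diagnosis = "DIAGNOSIS"
  )
}

#' Sample per-document style profiles
#'
#' Each report gets a style profile: section order (occasionally permuted),
#' dropped optional sections, digit vs number-word counts, ISO vs legacy
#' dates, and a phrasing-variant id per field. Patient information,
#' microscopic description and diagnosis are never dropped.
#'
#' @param config A [registry_config()] (its `style` element is used).
#' @param truth Ground-truth report tibble.
#' @return Tibble of style profiles, one row per document.
#' @export
sample_styles <- function(config, truth) {
  st <- config$style
  n <- nrow(truth)
  canon <- canonical_section_order()
  orders <- replicate(n, canon, simplify = FALSE)
  permute <- stats::runif(n) < st$permute_order_prob
  orders[permute] <- lapply(which(permute), function(i) sample(canon))
  variant_fields <- c(
    "phin", "biopsy_date", "dob", "sex", "glom_total", "glom_global",
    "glom_segmental", "crescents", "ifta", "em", "if_panel", "oxford",
    "ln", "dx", "dx_sec", "nondx", "gross"
  )
  styles <- tibble::tibble(
    doc_id = truth$doc_id,
    number_style = ifelse(stats::runif(n) < st$word_style_prob, "words", "digits"),
    date_style = ifelse(stats::runif(n) < st$legacy_date_prob, "legacy", "iso"),
    section_order = orders,
    drop_gross = stats::runif(n) < st$drop_gross_prob,
    drop_if = stats::runif(n) < st$drop_if_prob,
    drop_em = stats::runif(n) < st$drop_em_prob,
    micro_header = sample(c("MICROSCOPIC DESCRIPTION", "LIGHT MICROSCOPY"),
                          n, replace = TRUE, prob = c(0.8, 0.2)),
    gross_k = sample(1:3, n, replace = TRUE),
    gross_len = round(stats::runif(n, 0.8, 2.2), 1)
  )
  for (f in variant_fields) {
    styles[[paste0("v_", f)]] <- sample(1:3, n, replace = TRUE)
  }
  # nondiagnostic samples have no immunofluorescence or EM findings
  if (n > 0 && any(!truth$diagnostic)) {
    styles$drop_if[!truth$diagnostic] <- TRUE
    styles$drop_em[!truth$diagnostic] <- TRUE
  }
  styles
}

# a fact in a dropped section is absent from the ground truth too, so the
# round-trip contract (every truth field is recoverable) holds by design
apply_style_drops <- function(truth, styles) {
  stopifnot(identical(truth$doc_id, styles$doc_id))
  truth$em_effacement_pct[styles$drop_em] <- NA_integer_
  for (ab in paste0("if_", tolower(if_antibodies()))) {
    truth[[ab]][styles$drop_if] <- NA_integer_
  }
  truth
}

format_report_date <- function(d, style) {
  out <- format(d, "%Y-%m-%d")
  legacy <- style == "legacy"
  out[legacy] <- sprintf(
    "%02d-%s-%04d",
    lubridate::day(d[legacy]),
    month.abb[lubridate::month(d[legacy])],
    lubridate::year(d[legacy])
  )
  out[is.na(d)] <- NA_character_
  out
}

fill_slot <- function(text, slot, value) {
  stringr::str_replace(text, stringr::fixed(paste0("{", slot, "}")), value)
}

count_sentence <- function(tpls, variant, value, words) {
  out <- tpls[variant]
  token <- ifelse(words, number_to_words(pmin(value, 99)), as.character(value))
  token_cap <- ifelse(words, number_to_words(pmin(value, 99), capitalize = TRUE),
                      as.character(value))
  out <- fill_slot(out, "value", token)
  out <- fill_slot(out, "Value", token_cap)
  out[is.na(value)] <- NA_character_
  out
}

#' Render one field sentence
#'
#' Renders a single count-valued field through a given template variant and
#' number style; useful for exercising the extraction patterns against the
#' renderer's phrasing inventory (e.g. the three global-sclerosis variants).
#'
#' @param field Template field name (e.g. `"glomeruli_global_sclerosis"`).
#' @param value Integer value.
#' @param variant Template variant id (1-based).
#' @param number_style `"digits"` or `"words"`.
#' @param templates Template inventory from [default_templates()].
#' @return A sentence string.
#' @examples
#' render_field_sentence("glomeruli_global_sclerosis", 10, 1)
#' render_field_sentence("glomeruli_global_sclerosis", 10, 3, "words")
#' @export
render_field_sentence <- function(field, value, variant,
                                  number_style = "digits",
                                  templates = default_templates()) {
  tpls <- unlist(templates$fields[[field]]$templates)
  if (is.null(tpls) || variant > length(tpls)) {
    rlang::abort(paste0("No template variant ", variant, " for field '", field, "'"))
  }
  count_sentence(tpls, variant, as.integer(value), number_style == "words")
}

paste_lines <- function(...) {
  parts <- list(...)
  n <- max(vapply(parts, length, 1L))
  parts <- lapply(parts, function(p) rep_len(p, n))
  out <- rep("", n)
  for (p in parts) {
    add <- !is.na(p) & nzchar(p)
    out[add] <- ifelse(nzchar(out[add]), paste(out[add], p[add], sep = "\n"), p[add])
  }
  out
}

#' Render report documents
#'
#' Turns ground-truth biopsy records into plain-text report documents under
#' the given style profiles. Every non-absent fact appears exactly once,
#' phrased per the document's per-field template variants; counts are
#' rendered as English number words where the style says so.
#'
#' @param truth Ground-truth tibble from [generate_registry()].
#' @param styles Style tibble from [sample_styles()].
#' @param templates Template inventory from [default_templates()].
#' @param map Diagnosis map from [dx_map()].
#' @return Tibble with columns `doc_id`, `text`.
#' @export
render_reports <- function(truth, styles, templates = default_templates(),
                           map = dx_map()) {
  stopifnot(identical(truth$doc_id, styles$doc_id))
  n <- nrow(truth)
  if (n == 0) return(tibble::tibble(doc_id = character(), text = character()))
  tf <- function(f) unlist(templates$fields[[f]]$templates)
  words <- styles$number_style == "words"

  # patient information
  s_phin <- fill_slot(tf("phin")[styles$v_phin], "value", truth$patient_id)
  s_bxdate <- fill_slot(tf("biopsy_date")[styles$v_biopsy_date], "value",
                        format_report_date(truth$biopsy_date, styles$date_style))
  s_dob <- fill_slot(tf("dob")[styles$v_dob], "value",
                     format_report_date(truth$dob, styles$date_style))
  sex_full <- ifelse(truth$sex == "F", "Female", "Male")
  s_sex <- tf("sex")[styles$v_sex]
  s_sex <- fill_slot(s_sex, "value", truth$sex)
  s_sex <- fill_slot(s_sex, "value_full", sex_full)
  s_sex <- fill_slot(s_sex, "value_lower", tolower(sex_full))
  body_pi <- paste_lines(s_phin, s_bxdate, s_dob, s_sex)

  # gross description (no extracted facts)
  s_gross <- tf("gross_filler")[styles$v_gross]
  s_gross <- fill_slot(s_gross, "k", as.character(styles$gross_k))
  s_gross <- fill_slot(s_gross, "K", number_to_words(styles$gross_k, capitalize = TRUE))
  body_gd <- fill_slot(s_gross, "len", format(styles$gross_len, nsmall = 1, trim = TRUE))

  # microscopic description
  s_tot <- count_sentence(tf("glomeruli_total"), styles$v_glom_total,
                          truth$glomeruli_total, words)
  s_glob <- count_sentence(tf("glomeruli_global_sclerosis"), styles$v_glom_global,
                           truth$glomeruli_global_sclerosis, words)
  s_seg <- count_sentence(tf("glomeruli_segmental_sclerosis"), styles$v_glom_segmental,
                          truth$glomeruli_segmental_sclerosis, words)
  cres_v <- ifelse(styles$v_crescents == 3 &
                     dplyr::coalesce(truth$crescents_pct, 0L) > 0,
                   1L, styles$v_crescents)
  s_cres <- fill_slot(tf("crescents_pct")[cres_v], "value",
                      as.character(truth$crescents_pct))
  s_cres[is.na(truth$crescents_pct)] <- NA_character_
  s_ifta <- tf("ifta_grade")[styles$v_ifta]
  s_ifta <- fill_slot(s_ifta, "value_no",
                      ifelse(truth$ifta_grade == "none", "no", truth$ifta_grade))
  s_ifta <- fill_slot(s_ifta, "value", truth$ifta_grade)
  s_ifta[is.na(truth$ifta_grade)] <- NA_character_
  body_md <- paste_lines(s_tot, s_glob, s_seg, s_cres, s_ifta)

  # immunofluorescence panel
  if_parts <- list()
  for (ab in if_antibodies()) {
    v <- truth[[paste0("if_", tolower(ab))]]
    pos <- fill_slot(fill_slot(tf("if_positive")[styles$v_if_panel], "ab", ab),
                     "value", as.character(v))
    neg <- fill_slot(tf("if_negative")[styles$v_if_panel], "ab", ab)
    sent <- ifelse(is.na(v), NA_character_, ifelse(v > 0, pos, neg))
    if_parts[[ab]] <- sent
  }
  body_if <- do.call(paste_lines, if_parts)

  # electron microscopy
  s_em <- fill_slot(tf("em_effacement_pct")[styles$v_em], "value",
                    as.character(truth$em_effacement_pct))
  s_em[is.na(truth$em_effacement_pct)] <- NA_character_
  body_em <- s_em

  # diagnosis
  lab_primary <- dx_label(truth$primary_dx, map)
  s_dx <- fill_slot(tf("dx_primary")[styles$v_dx], "label", lab_primary)
  s_dx[!truth$diagnostic] <- tf("nondiagnostic")[styles$v_nondx[!truth$diagnostic]]
  lab_sec <- dx_label(truth$secondary_dx, map)
  s_sec <- fill_slot(tf("dx_secondary")[styles$v_dx_sec], "label", lab_sec)
  s_sec[is.na(truth$secondary_dx)] <- NA_character_
  s_ox <- tf("oxford")[styles$v_oxford]
  for (slot in c("m", "e", "s", "t", "c")) {
    s_ox <- fill_slot(s_ox, slot, as.character(truth[[paste0("oxford_", slot)]]))
  }
  s_ox[is.na(truth$oxford_m)] <- NA_character_
  s_ln <- tf("ln_indices")[styles$v_ln]
  s_ln <- fill_slot(s_ln, "a", as.character(truth$ln_activity))
  s_ln <- fill_slot(s_ln, "c", as.character(truth$ln_chronicity))
  s_ln <- fill_slot(s_ln, "a_words", number_to_words(pmin(dplyr::coalesce(truth$ln_activity, 0L), 99)))
  s_ln <- fill_slot(s_ln, "c_words", number_to_words(pmin(dplyr::coalesce(truth$ln_chronicity, 0L), 99)))
  s_ln[is.na(truth$ln_activity)] <- NA_character_
  body_dx <- paste_lines(s_dx, s_sec, s_ox, s_ln)

  bodies <- list(
    patient_information = body_pi,
    gross_description = ifelse(styles$drop_gross, "", body_gd),
    microscopic_description = body_md,
    immunofluorescence = ifelse(styles$drop_if, "", body_if),
    electron_microscopy = ifelse(styles$drop_em, "", body_em),
    diagnosis = body_dx
  )

  text <- vapply(seq_len(n), function(i) {
    secs <- character(0)
    hdr <- section_headers(styles$micro_header[i])
    for (sec in styles$section_order[[i]]) {
      b <- bodies[[sec]][i]
      if (!is.na(b) && nzchar(b)) {
        secs <- c(secs, paste0(hdr[[sec]], ":\n", b))
      }
    }
    paste(secs, collapse = "\n\n")
  }, character(1))

  tibble::tibble(doc_id = truth$doc_id, text = text)
}

#' Render a single report document
#'
#' @param record One-row ground-truth tibble.
#' @param style One-row style tibble (see [sample_styles()]).
#' @inheritParams render_reports
#' @return One-row tibble with `doc_id` and `text`.
#' @export
render_report <- function(record, style, templates = default_templates(),
                          map = dx_map()) {
  stopifnot(nrow(record) == 1, nrow(style) == 1)
  render_reports(record, style, templates, map)
}
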