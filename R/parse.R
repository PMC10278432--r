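#' Load the extraction pattern library
#'
#' Patterns are data: a YAML file declaring, per field, the target section,
#' the value type and an ordered list of regular expressions with one
#' capture slot each. `{{COUNT}}` expands to an alternation matching digit
#' strings or English number words 0-99; `{{DATE}}` to ISO-8601 or
#' DD-Mon-YYYY dates. The library is versioned alongside the package so the
#' iterative refinement loop is a config change, not a code change.
#'
#' @param path Path to a pattern YAML; `NULL` for the packaged default.
#' @return Nested pattern list.
#' @export
default_patterns <- function(path = NULL) {
  if (is.null(path) && !is.null(the_cache$patterns)) return(the_cache$patterns)
  p <- if (is.null(path)) {
    system.file("extdata", "patterns.yaml", package = "glomreg")
  } else {
    path
  }
  pat <- yaml::read_yaml(p)
  date_re <- "(\\d{4}-\\d{2}-\\d{2}|\\d{1,2}-[A-Za-z]{3}-\\d{4})"
  count_re <- count_token_regex()
  for (f in names(pat$fields)) {
    for (i in seq_along(pat$fields[[f]]$patterns)) {
      re <- pat$fields[[f]]$patterns[[i]]$regex
      re <- gsub("{{COUNT}}", count_re, re, fixed = TRUE)
      re <- gsub("{{DATE}}", date_re, re, fixed = TRUE)
      pat$fields[[f]]$patterns[[i]]$regex <- re
    }
  }
  if (is.null(path)) the_cache$patterns <- pat
  pat
}

section_names <- function() canonical_section_order()

header_regex <- function(synonyms) {
  stringr::regex(
    paste0("^[ \\t]*(?:", paste(synonyms, collapse = "|"), ")[ \\t]*:?[ \\t]*$"),
    ignore_case = TRUE, multiline = TRUE
  )
}

# locate the six canonical sections in every document at once; returns a
# list with per-section content start/end matrices and extracted text
segment_all <- function(texts, patterns = default_patterns()) {
  n <- length(texts)
  secs <- names(patterns$sections)
  hdr_start <- matrix(NA_integer_, n, length(secs), dimnames = list(NULL, secs))
  hdr_end <- hdr_start
  for (s in secs) {
    loc <- stringr::str_locate_all(texts, header_regex(patterns$sections[[s]]))
    first <- t(vapply(loc, function(m) {
      if (nrow(m) == 0) c(NA_integer_, NA_integer_) else as.integer(m[1, ])
    }, integer(2)))
    hdr_start[, s] <- first[, 1]
    hdr_end[, s] <- first[, 2]
  }
  content_start <- hdr_start
  content_end <- hdr_start
  nch <- nchar(texts)
  for (i in seq_len(n)) {
    hs <- hdr_start[i, ]
    found <- which(!is.na(hs))
    ord <- found[order(hs[found])]
    for (k in seq_along(ord)) {
      s <- ord[k]
      content_start[i, s] <- hdr_end[i, s] + 1L
      content_end[i, s] <- if (k < length(ord)) hs[ord[k + 1]] - 1L else nch[i]
    }
  }
  text_mat <- matrix(NA_character_, n, length(secs), dimnames = list(NULL, secs))
  for (s in secs) {
    ok <- !is.na(content_start[, s])
    text_mat[ok, s] <- stringr::str_sub(texts[ok], content_start[ok, s],
                                        content_end[ok, s])
  }
  list(start = content_start, end = content_end, text = text_mat)
}

#' Segment one report into its canonical sections
#'
#' Section headers are matched case-insensitively on standalone lines using
#' a synonym list per section (e.g. "LIGHT MICROSCOPY" for the microscopic
#' description). Each detected header owns the span up to the next header or
#' the end of the document; undetected sections are marked absent.
#'
#' @param text A single report document.
#' @param patterns Pattern library from [default_patterns()].
#' @return Tibble with one row per canonical section: `section`, `present`,
#'   `start`, `end` (content span, document coordinates).
#' @export
segment_sections <- function(text, patterns = default_patterns()) {
  stopifnot(length(text) == 1, nzchar(text))
  seg <- segment_all(text, patterns)
  out <- tibble::tibble(
    section = colnames(seg$start),
    present = !is.na(seg$start[1, ]),
    start = as.integer(seg$start[1, ]),
    end = as.integer(seg$end[1, ])
  )
  if (!any(out$present)) {
    rlang::abort("Unparseable document: no recognizable section header",
                 class = "glomreg_unparseable_error")
  }
  out[order(is.na(out$start), out$start), ]
}

# --- post-processors --------------------------------------------------------

postprocess_token <- function(token, type) {
  switch(type,
    count = as.character(normalize_number_word(tolower(token))),
    percent = ifelse(tolower(token) == "no", "0", as.character(as.integer(token))),
    grade = ifelse(tolower(token) == "no", "none", tolower(token)),
    date = as.character(parse_report_date(token)),
    sex = toupper(substr(token, 1, 1)),
    code = token,
    intensity = as.character(as.integer(token)),
    token
  )
}

parse_report_date <- function(token) {
  iso <- grepl("^\\d{4}-", token)
  out <- rep(as.Date(NA), length(token))
  out[iso] <- as.Date(token[iso])
  if (any(!iso)) {
    parts <- stringr::str_match(token[!iso], "^(\\d{1,2})-([A-Za-z]{3})-(\\d{4})$")
    mon <- match(tolower(parts[, 3]), tolower(month.abb))
    out[!iso] <- as.Date(ifelse(
      is.na(mon), NA,
      sprintf("%s-%02d-%02d", parts[, 4], mon, as.integer(parts[, 2]))
    ))
  }
  out
}

# --- core extraction engine -------------------------------------------------

# run every pattern of a field spec over a vector of texts; `base` gives the
# document coordinate of each text's first character. Pools all matches of
# all patterns: a single distinct value wins, disagreement is CONFLICT,
# no match is MISSING.
extract_field_vec <- function(texts, base, spec) {
  n <- length(texts)
  value <- rep(NA_character_, n)
  pattern_id <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  status <- rep("missing", n)

  tokens <- vector("list", n)
  for (p in spec$patterns) {
    re <- stringr::regex(p$regex, ignore_case = TRUE)
    caps <- stringr::str_match_all(texts, re)
    locs <- stringr::str_locate_all(texts, re)
    for (i in seq_len(n)) {
      m <- caps[[i]]
      if (is.null(m) || nrow(m) == 0) next
      vals <- postprocess_token(m[, 2], spec$type)
      tokens[[i]] <- c(tokens[[i]], vals)
      if (is.na(pattern_id[i])) {
        pattern_id[i] <- p$id
        start[i] <- base[i] + locs[[i]][1, 1] - 1L
        end[i] <- base[i] + locs[[i]][1, 2] - 1L
      }
    }
  }
  for (i in seq_len(n)) {
    tk <- unique(tokens[[i]])
    if (length(tk) == 0) next
    if (length(tk) > 1) {
      status[i] <- "conflict"
    } else {
      rng <- spec$range
      num <- suppressWarnings(as.numeric(tk))
      if (!is.null(rng) && !is.na(num) && (num < rng[1] || num > rng[2])) {
        status[i] <- "conflict"
      } else {
        value[i] <- tk
        status[i] <- "ok"
      }
    }
  }
  tibble::tibble(value = value, pattern_id = pattern_id, start = start,
                 end = end, status = status)
}

#' Extract a single field from section text
#'
#' Applies a field's ordered pattern list to a piece of text. All matches of
#' all patterns are pooled: a single distinct value is returned, disagreeing
#' matches yield status `"conflict"` (never a silently wrong value), and no
#' match yields `"missing"` (missingness is data, not an error).
#'
#' @param section_text Text to search (one string).
#' @param spec Field spec: a list with `type`, `patterns` (list of
#'   `id`/`regex`), and optionally `range`; e.g. an element of
#'   `default_patterns()$fields`.
#' @return A list with `value` (typed), `pattern_id`, `start`, `end`,
#'   `status`.
#' @examples
#' spec <- default_patterns()$fields$glomeruli_global_sclerosis
#' extract_field("There are 10 globally sclerosed glomeruli", spec)$value
#' @export
extract_field <- function(section_text, spec) {
  stopifnot(length(section_text) == 1)
  res <- extract_field_vec(section_text, 1L, spec)
  list(
    value = typed_value(res$value, spec$type),
    pattern_id = res$pattern_id,
    start = res$start,
    end = res$end,
    status = res$status
  )
}

typed_value <- function(value, type) {
  switch(type,
    count = as.integer(value),
    percent = as.integer(value),
    intensity = as.integer(value),
    date = as.Date(value),
    value
  )
}

# --- panel / score extractors ----------------------------------------------

if_panel_vec <- function(texts, base, patterns = default_patterns()) {
  spec <- patterns$if_panel
  abs <- spec$antibodies
  n <- length(texts)
  out <- list()
  prov <- list()
  for (ab in abs) {
    pos_re <- gsub("{{AB}}", ab, spec$intensity_regex, fixed = TRUE)
    neg_re <- gsub("{{AB}}", ab, spec$negative_regex, fixed = TRUE)
    pos <- extract_field_vec(texts, base, list(
      type = "intensity",
      patterns = list(list(id = paste0("if_", tolower(ab), "_intensity"),
                           regex = pos_re))
    ))
    neg_loc <- stringr::str_locate_all(texts, stringr::regex(neg_re, ignore_case = TRUE))
    neg_hit <- vapply(neg_loc, nrow, 1L) > 0
    col <- pos
    for (i in which(neg_hit)) {
      if (col$status[i] == "missing") {
        col$value[i] <- "0"
        col$status[i] <- "ok"
        col$pattern_id[i] <- paste0("if_", tolower(ab), "_negative")
        col$start[i] <- base[i] + neg_loc[[i]][1, 1] - 1L
        col$end[i] <- base[i] + neg_loc[[i]][1, 2] - 1L
      } else if (col$status[i] == "ok" && col$value[i] != "0") {
        col$status[i] <- "conflict"
        col$value[i] <- NA_character_
      }
    }
    out[[paste0("if_", tolower(ab))]] <- col
  }
  out
}

#' Extract the immunofluorescence panel
#'
#' Maps each of the seven antibodies (IgG, IgA, IgM, C3, C1q, kappa,
#' lambda) to a staining intensity 0-3 or `NA` (missing). "Negative" / "no
#' staining" phrasing maps to 0.
#'
#' @param section_text Immunofluorescence section text (one string).
#' @param patterns Pattern library from [default_patterns()].
#' @return Named integer vector over the seven antibodies (`NA` = missing).
#' @examples
#' extract_if_panel("IgA is 3+ in a granular pattern. C1q: negative.")
#' @export
extract_if_panel <- function(section_text, patterns = default_patterns()) {
  stopifnot(length(section_text) == 1)
  res <- if_panel_vec(section_text, 1L, patterns)
  vapply(res, function(col) {
    if (col$status[1] == "ok") as.integer(col$value[1]) else NA_integer_
  }, integer(1))
}

oxford_vec <- function(texts, base, patterns = default_patterns()) {
  re <- stringr::regex(patterns$oxford$regex, ignore_case = TRUE)
  caps <- stringr::str_match_all(texts, re)
  locs <- stringr::str_locate_all(texts, re)
  n <- length(texts)
  mat <- matrix(NA_integer_, n, 5,
                dimnames = list(NULL, c("oxford_m", "oxford_e", "oxford_s",
                                        "oxford_t", "oxford_c")))
  status <- rep("missing", n)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- caps[[i]]
    if (is.null(m) || nrow(m) == 0) next
    tuples <- unique(apply(m[, 2:6, drop = FALSE], 1, paste, collapse = ""))
    if (length(tuples) > 1) {
      status[i] <- "conflict"
    } else {
      mat[i, ] <- as.integer(m[1, 2:6])
      status[i] <- "ok"
      start[i] <- base[i] + locs[[i]][1, 1] - 1L
      end[i] <- base[i] + locs[[i]][1, 2] - 1L
    }
  }
  list(values = mat, status = status, start = start, end = end)
}

#' Extract the Oxford MEST-C score
#'
#' Recognizes spaced, compact and comma-separated MEST-C phrasings
#' ("Oxford score M1 E0 S1 T0 C0", "MEST-C: M1E1S1T2C1"). Disagreeing
#' mentions yield a conflict rather than a silently wrong score.
#'
#' @param section_text Text to search (one string).
#' @param patterns Pattern library from [default_patterns()].
#' @return Named integer vector `(M, E, S, T, C)`, all `NA` when absent.
#' @export
extract_oxford <- function(section_text, patterns = default_patterns()) {
  stopifnot(length(section_text) == 1)
  res <- oxford_vec(section_text, 1L, patterns)
  out <- res$values[1, ]
  names(out) <- c("M", "E", "S", "T", "C")
  if (res$status[1] == "conflict") {
    attr(out, "status") <- "conflict"
  }
  out
}

#' Extract lupus nephritis activity and chronicity indices
#'
#' Activity is scored 0-24 and chronicity 0-12; both digit and number-word
#' phrasing are recognized. Out-of-range values are flagged as conflicts.
#'
#' @param section_text Text to search (one string).
#' @param patterns Pattern library from [default_patterns()].
#' @return Named integer vector `c(activity, chronicity)` (`NA` = missing).
#' @export
extract_ln_indices <- function(section_text, patterns = default_patterns()) {
  stopifnot(length(section_text) == 1)
  a <- extract_field(section_text, patterns$fields$ln_activity)
  c_ <- extract_field(section_text, patterns$fields$ln_chronicity)
  out <- c(
    activity = if (a$status == "ok") a$value else NA_integer_,
    chronicity = if (c_$status == "ok") c_$value else NA_integer_
  )
  attr(out, "status") <- c(a$status, c_$status)
  out
}

# --- diagnosis extraction ---------------------------------------------------

diagnosis_vec <- function(texts, base, patterns = default_patterns(),
                          map = dx_map()) {
  n <- length(texts)
  nondx_re <- stringr::regex(patterns$diagnosis$nondiagnostic_regex,
                             ignore_case = TRUE)
  nondx <- !is.na(texts) & stringr::str_detect(texts, nondx_re)

  secondary <- rep(NA_character_, n)
  masked <- texts
  for (re in patterns$diagnosis$secondary_regexes) {
    rex <- stringr::regex(re, ignore_case = TRUE)
    m <- stringr::str_match(masked, rex)
    hit <- !is.na(m[, 2]) & is.na(secondary)
    secondary[hit] <- trimws(m[hit, 2])
    masked <- stringr::str_replace(masked, rex, "")
  }

  syn <- synonym_table(map)
  low <- tolower(masked)
  primary <- rep(NA_character_, n)
  prim_start <- rep(NA_integer_, n)
  best_start <- rep(Inf, n)
  for (k in seq_len(nrow(syn))) {
    pos <- stringr::str_locate(low, stringr::fixed(tolower(syn$synonyms[k])))[, 1]
    better <- !is.na(pos) & pos < best_start
    primary[better] <- syn$synonyms[k]
    prim_start[better] <- pos[better]
    best_start[better] <- pos[better]
  }
  primary[nondx] <- NA_character_
  secondary[nondx] <- NA_character_
  tibble::tibble(
    nondiagnostic = nondx,
    primary_text = primary,
    secondary_text = secondary,
    start = ifelse(is.na(prim_start), NA_integer_, base + prim_start - 1L)
  )
}

# --- whole-document parsing -------------------------------------------------

scalar_field_names <- function() {
  c(
    phin = "patient_id", biopsy_date = "biopsy_date", dob = "dob", sex = "sex",
    glomeruli_total = "glomeruli_total",
    glomeruli_global_sclerosis = "glomeruli_global_sclerosis",
    glomeruli_segmental_sclerosis = "glomeruli_segmental_sclerosis",
    crescents_pct = "crescents_pct", ifta_grade = "ifta_grade",
    em_effacement_pct = "em_effacement_pct",
    ln_activity = "ln_activity", ln_chronicity = "ln_chronicity"
  )
}

#' Parse a corpus of report documents
#'
#' Segments each document into sections, extracts every registry variable
#' through the pattern library, and assembles one structured row per
#' document with per-field provenance (matched pattern, character offsets)
#' attached as the `"provenance"` attribute. Field search is restricted to
#' the field's declared section, falling back to whole-document search when
#' the section is absent (except the immunofluorescence panel, which
#' requires its section). `parse_status` is `"nondiagnostic"` when the
#' diagnosis section matches the inadequate-sampling patterns, `"conflict"`
#' when any field has disagreeing matches, `"unparseable"` when no section
#' header is recognizable, otherwise `"ok"`.
#'
#' @param documents Tibble with columns `doc_id`, `text`.
#' @param patterns Pattern library from [default_patterns()].
#' @param map Diagnosis map from [dx_map()] (synonyms drive diagnosis-string
#'   recognition; canonical codes are assigned by [classify_reports()]).
#' @return Tibble, one row per document, with the extracted fields,
#'   `primary_dx_text`/`secondary_dx_text`, and `parse_status`; provenance
#'   in `attr(, "provenance")`.
#' @export
parse_reports <- function(documents, patterns = default_patterns(),
                          map = dx_map()) {
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  n <- nrow(documents)
  if (n == 0) {
    out <- truth_schema()[, setdiff(names(truth_schema()),
                                    c("patient_key", "role", "episode_id"))]
    out$primary_dx_text <- character(0)
    out$secondary_dx_text <- character(0)
    out$parse_status <- character(0)
    attr(out, "provenance") <- tibble::tibble(
      doc_id = character(), field = character(), value = character(),
      pattern_id = character(), start = integer(), end = integer(),
      status = character()
    )
    return(out)
  }
  texts <- documents$text
  seg <- segment_all(texts, patterns)
  no_sections <- rowSums(!is.na(seg$start)) == 0

  pick_section <- function(sec, fallback = TRUE) {
    txt <- seg$text[, sec]
    base <- seg$start[, sec]
    if (fallback) {
      absent <- is.na(txt)
      txt[absent] <- texts[absent]
      base[absent] <- 1L
    }
    list(text = txt, base = base)
  }

  out <- tibble::tibble(doc_id = documents$doc_id)
  prov <- list()
  add_prov <- function(field, res) {
    prov[[length(prov) + 1]] <<- tibble::tibble(
      doc_id = documents$doc_id, field = field, value = res$value,
      pattern_id = res$pattern_id, start = res$start, end = res$end,
      status = res$status
    )
  }

  conflict_any <- rep(FALSE, n)
  for (f in names(patterns$fields)) {
    spec <- patterns$fields[[f]]
    tgt <- pick_section(spec$section)
    res <- extract_field_vec(tgt$text, tgt$base, spec)
    col <- scalar_field_names()[[f]]
    out[[col]] <- typed_value(res$value, spec$type)
    conflict_any <- conflict_any | res$status == "conflict"
    add_prov(col, res)
  }

  iftxt <- seg$text[, "immunofluorescence"]
  ifbase <- seg$start[, "immunofluorescence"]
  have_if <- !is.na(iftxt)
  panel <- if_panel_vec(ifelse(have_if, iftxt, ""), dplyr::coalesce(ifbase, 1L),
                        patterns)
  for (ab in names(panel)) {
    col <- panel[[ab]]
    col$value[!have_if] <- NA_character_
    col$status[!have_if] <- "missing"
    out[[ab]] <- as.integer(col$value)
    conflict_any <- conflict_any | col$status == "conflict"
    add_prov(ab, col)
  }

  dx_sec <- pick_section("diagnosis")
  ox <- oxford_vec(dx_sec$text, dx_sec$base, patterns)
  for (j in seq_len(5)) {
    out[[colnames(ox$values)[j]]] <- unname(ox$values[, j])
  }
  conflict_any <- conflict_any | ox$status == "conflict"
  add_prov("oxford", tibble::tibble(
    value = apply(ox$values, 1, function(r) {
      if (all(is.na(r))) NA_character_ else paste(r, collapse = "")
    }),
    pattern_id = ifelse(ox$status == "ok", "oxford_mestc", NA_character_),
    start = ox$start, end = ox$end, status = ox$status
  ))

  dxr <- diagnosis_vec(dx_sec$text, dx_sec$base, patterns, map)
  out$primary_dx_text <- dxr$primary_text
  out$secondary_dx_text <- dxr$secondary_text
  out$diagnostic <- !dxr$nondiagnostic & !is.na(dxr$primary_text)
  add_prov("primary_dx", tibble::tibble(
    value = dxr$primary_text, pattern_id = "dx_synonym",
    start = dxr$start, end = NA_integer_,
    status = ifelse(is.na(dxr$primary_text), "missing", "ok")
  ))

  out$parse_status <- dplyr::case_when(
    no_sections ~ "unparseable",
    dxr$nondiagnostic ~ "nondiagnostic",
    conflict_any ~ "conflict",
    TRUE ~ "ok"
  )
  if (any(no_sections)) {
    rlang::warn(paste0(sum(no_sections), " document(s) had no recognizable ",
                       "section headers and were marked unparseable"))
    for (col in setdiff(names(out), c("doc_id", "parse_status"))) {
      out[[col]][no_sections] <- NA
    }
  }
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Parse a single report document
#'
#' @param text One report document (a string).
#' @inheritParams parse_reports
#' @return One-row tibble as from [parse_reports()]; errors if the document
#'   has no recognizable section header.
#' @export
parse_report <- function(text, patterns = default_patterns(), map = dx_map()) {
  segment_sections(text, patterns) # errors on unparseable input
  parse_reports(tibble::tibble(doc_id = "doc1", text = text), patterns, map)
}

#' Canonicalize parsed diagnoses and assign disease groups
#'
#' Adds canonical diagnosis codes (`primary_dx`, `secondary_dx`), the broad
#' disease group and the common-GN flag to a parsed-report tibble.
#'
#' @param parsed Tibble from [parse_reports()].
#' @param map Diagnosis map from [dx_map()].
#' @return The input with classification columns added.
#' @export
classify_reports <- function(parsed, map = dx_map()) {
  parsed$primary_dx <- canonicalize_dx_quiet(parsed$primary_dx_text, map)
  parsed$secondary_dx <- canonicalize_dx_quiet(parsed$secondary_dx_text, map)
  parsed$broad_group <- ifelse(
    is.na(parsed$primary_dx), NA_character_,
    broad_group(parsed$primary_dx, map)
  )
  parsed$common_gn <- is_common_gn(parsed$primary_dx, map)
  parsed
}

canonicalize_dx_quiet <- function(x, map) {
  out <- rep(NA_character_, length(x))
  has <- !is.na(x)
  if (any(has)) out[has] <- canonicalize_dx(x[has], map)
  out
}
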