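#' Load the diagnosis map
#'
#' The diagnosis map is data, not code: a YAML file giving, for each canonical
#' diagnosis code, a display label, the broad disease group, the common-GN
#' flag and a synonym list. The packaged default covers the diagnoses of a
#' native kidney biopsy service; users can point at an edited copy to extend
#' the code set or reassign groups without touching the package.
#'
#' @param path Path to a YAML diagnosis map; `NULL` for the packaged default.
#' @return A tibble with one row per canonical code: `code`, `label`,
#'   `group`, `common_gn`, and a list-column `synonyms`.
#' @export
dx_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dx_map.yaml", package = "glomreg")
  }
  raw <- yaml::read_yaml(path)$codes
  tibble::tibble(
    code = names(raw),
    label = unname(purrr::map_chr(raw, "label")),
    group = unname(purrr::map_chr(raw, "group")),
    common_gn = unname(purrr::map_lgl(raw, "common_gn")),
    synonyms = unname(purrr::map(raw, ~ as.character(.x$synonyms)))
  )
}

#' Broad disease groups
#'
#' Biopsy diagnoses are classified into seven broad groups (proliferative GN,
#' nonproliferative GN, diabetic nephropathy, tubulointerstitial, vascular,
#' deposition, hereditary), plus `unclassified` for diagnoses outside the
#' scheme; nondiagnostic biopsies are not classified.
#'
#' @return Character vector of group identifiers.
#' @export
disease_groups <- function() {
  c(
    "proliferative_gn", "nonproliferative_gn", "diabetic_nephropathy",
    "tubulointerstitial", "vascular", "deposition", "hereditary",
    "unclassified"
  )
}

#' Canonical codes of the eight common glomerular diseases
#' @param map Diagnosis map tibble from [dx_map()].
#' @return Character vector of codes.
#' @export
common_gn_codes <- function(map = dx_map()) {
  map$code[map$common_gn]
}

# synonym table ordered longest-first so e.g. "secondary focal segmental
# glomerulosclerosis" wins over the embedded "focal segmental
# glomerulosclerosis"
synonym_table <- function(map = dx_map()) {
  tbl <- tidyr::unnest(map[, c("code", "synonyms")], "synonyms")
  tbl[order(-nchar(tbl$synonyms)), ]
}

#' Canonicalize a free-text diagnosis string
#'
#' Matches a curated, case-insensitive synonym dictionary longest-match-first.
#' Strings matching no synonym map to `"other"` with a warning.
#'
#' @param dx_text Character vector of diagnosis strings.
#' @param map Diagnosis map tibble from [dx_map()].
#' @return Character vector of canonical diagnosis codes.
#' @examples
#' canonicalize_dx("membranous glomerulonephritis")
#' canonicalize_dx("crescentic ANCA-associated glomerulonephritis")
#' @export
canonicalize_dx <- function(dx_text, map = dx_map()) {
  stopifnot(is.character(dx_text))
  syn <- synonym_table(map)
  out <- rep(NA_character_, length(dx_text))
  txt <- tolower(dx_text)
  for (i in seq_len(nrow(syn))) {
    hit <- is.na(out) &
      stringr::str_detect(txt, stringr::fixed(tolower(syn$synonyms[i])))
    out[hit] <- syn$code[i]
  }
  unmatched <- is.na(out) & !is.na(dx_text) & nzchar(trimws(dx_text))
  if (any(unmatched)) {
    rlang::warn(paste0(
      "Unmatched diagnosis string(s) mapped to 'other': ",
      paste(utils::head(unique(dx_text[unmatched]), 5), collapse = "; ")
    ))
    out[unmatched] <- "other"
  }
  out
}

#' Broad-group assignment for a canonical diagnosis code
#'
#' Total over all codes: every diagnostic code belongs to exactly one broad
#' group; `nondiagnostic` (and codes outside the scheme) map to
#' `unclassified`.
#'
#' @param code Character vector of canonical codes.
#' @param map Diagnosis map tibble from [dx_map()].
#' @return Character vector of group identifiers.
#' @export
broad_group <- function(code, map = dx_map()) {
  grp <- map$group[match(code, map$code)]
  bad <- !is.na(code) & is.na(grp)
  if (any(bad)) {
    rlang::abort(paste0(
      "Unknown diagnosis code(s): ", paste(unique(code[bad]), collapse = ", ")
    ))
  }
  grp
}

#' Is a code one of the eight common glomerular diseases?
#'
#' @inheritParams broad_group
#' @return Logical vector.
#' @export
is_common_gn <- function(code, map = dx_map()) {
  flag <- map$common_gn[match(code, map$code)]
  flag[is.na(code)] <- NA
  dplyr::coalesce(flag, FALSE)
}

#' Display label for a canonical diagnosis code
#' @inheritParams broad_group
#' @return Character vector of labels.
#' @export
dx_label <- function(code, map = dx_map()) {
  map$label[match(code, map$code)]
}
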