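sample_report <- function() {
  paste(
    "PATIENT INFORMATION:",
    "PHIN: 123456789",
    "Date of biopsy: 2008-05-14",
    "Date of birth: 1970-01-02",
    "Sex: F",
    "",
    "GROSS DESCRIPTION:",
    "The specimen consists of 2 cores of tan-brown tissue measuring up to 1.5 cm.",
    "",
    "MICROSCOPIC DESCRIPTION:",
    "The biopsy contains 20 glomeruli.",
    "There are 10 globally sclerosed glomeruli.",
    "There are 2 segmentally sclerosed glomeruli.",
    "Cellular crescents are present in 5% of glomeruli.",
    "There is mild interstitial fibrosis and tubular atrophy.",
    "",
    "IMMUNOFLUORESCENCE:",
    "IgG is negative.",
    "IgA is 3+ in a granular pattern.",
    "IgM: 1+.",
    "C3 shows 2+ staining.",
    "C1q: negative.",
    "kappa shows no staining.",
    "lambda is 1+ in a granular pattern.",
    "",
    "ELECTRON MICROSCOPY:",
    "Electron microscopy demonstrates foot process effacement involving 30% of the capillary surface.",
    "",
    "DIAGNOSIS:",
    "IgA nephropathy.",
    "Oxford score M1 E0 S1 T0 C0.",
    sep = "\n"
  )
}

test_that("section segmentation finds canonical, permuted and absent layouts", {
  doc <- sample_report()
  seg <- segment_sections(doc)
  expect_true(all(seg$present))
  expect_identical(seg$section[order(seg$start)],
                   canonical_section_order())

  # diagnosis first: same sections found, spans reflect document order
  parts <- strsplit(doc, "\n\n")[[1]]
  permuted <- paste(c(parts[6], parts[1:5]), collapse = "\n\n")
  seg2 <- segment_sections(permuted)
  expect_true(all(seg2$present))
  expect_identical(seg2$section[which.min(seg2$start)], "diagnosis")

  # EM absent: five sections, EM marked absent
  no_em <- paste(parts[-5], collapse = "\n\n")
  seg3 <- segment_sections(no_em)
  expect_identical(sum(seg3$present), 5L)
  expect_false(seg3$present[seg3$section == "electron_microscopy"])

  expect_error(segment_sections("no headers anywhere in this text"),
               class = "glomreg_unparseable_error")
})

test_that("section header synonyms are recognized", {
  doc <- sub("MICROSCOPIC DESCRIPTION:", "LIGHT MICROSCOPY:", sample_report())
  seg <- segment_sections(doc)
  expect_true(seg$present[seg$section == "microscopic_description"])
  parsed <- parse_report(doc)
  expect_identical(parsed$glomeruli_total, 20L)
})

test_that("the glomerulus-count extractor handles all printed phrasing variants", {
  spec <- default_patterns()$fields$glomeruli_global_sclerosis
  variants <- c(
    "There are 10 globally sclerosed glomeruli",
    "The number of globally sclerotic glomeruli is 10",
    "Ten glomeruli are globally sclerosed"
  )
  for (v in variants) {
    res <- extract_field(v, spec)
    expect_identical(res$value, 10L, info = v)
    expect_identical(res$status, "ok")
  }
  # no glomerulus sentence: missing, not an error
  res <- extract_field("Tubules appear unremarkable.", spec)
  expect_identical(res$status, "missing")
  expect_true(is.na(res$value))
})

test_that("disagreeing matches yield a conflict, never a silently wrong value", {
  spec <- default_patterns()$fields$glomeruli_global_sclerosis
  two <- paste(
    "There are 10 globally sclerosed glomeruli.",
    "The number of globally sclerotic glomeruli is 12.",
    sep = "\n"
  )
  res <- extract_field(two, spec)
  expect_identical(res$status, "conflict")
  expect_true(is.na(res$value))
  # agreeing repeats are not a conflict
  agree <- paste(
    "There are 10 globally sclerosed glomeruli.",
    "Ten glomeruli are globally sclerosed.",
    sep = "\n"
  )
  expect_identical(extract_field(agree, spec)$status, "ok")

  doc <- sub("There are 10 globally sclerosed glomeruli.",
             two, sample_report(), fixed = TRUE)
  parsed <- parse_report(doc)
  expect_identical(parsed$parse_status, "conflict")
  expect_true(is.na(parsed$glomeruli_global_sclerosis))
})

test_that("the immunofluorescence panel maps antibodies to intensities", {
  panel <- extract_if_panel("IgA is 3+ granular mesangial")
  expect_identical(panel[["if_iga"]], 3L)
  expect_true(all(is.na(panel[setdiff(names(panel), "if_iga")])))

  panel2 <- extract_if_panel("C3 2+, C1q negative")
  expect_identical(panel2[["if_c3"]], 2L)
  expect_identical(panel2[["if_c1q"]], 0L)

  empty <- extract_if_panel("")
  expect_true(all(is.na(empty)))
})

test_that("Oxford MEST-C parsing covers spaced, compact and listed forms", {
  expect_identical(unname(extract_oxford("Oxford score M1 E0 S1 T0 C0")),
                   c(1L, 0L, 1L, 0L, 0L))
  expect_identical(unname(extract_oxford("MEST-C: M1E1S1T2C1")),
                   c(1L, 1L, 1L, 2L, 1L))
  expect_identical(unname(extract_oxford("Oxford classification: M0, E0, S1, T1, C0")),
                   c(0L, 0L, 1L, 1L, 0L))
  expect_true(all(is.na(extract_oxford("no score mentioned"))))
})

test_that("lupus nephritis indices parse from digit and number-word forms", {
  r <- extract_ln_indices("activity index 6/24, chronicity index 3/12")
  expect_identical(as.integer(r), c(6L, 3L))
  r2 <- extract_ln_indices("Activity index of six out of 24 and chronicity index of three out of 12.")
  expect_identical(as.integer(r2), c(6L, 3L))
  r3 <- extract_ln_indices("no indices reported")
  expect_true(all(is.na(r3)))
  # out-of-range values are flagged, not silently accepted
  r4 <- extract_ln_indices("activity index 30/24, chronicity index 3/12")
  expect_true(is.na(r4[["activity"]]))
  expect_identical(attr(r4, "status")[1], "conflict")
})

test_that("a full document parses to its structured record", {
  parsed <- parse_report(sample_report())
  expect_identical(parsed$parse_status, "ok")
  expect_identical(parsed$patient_id, "123456789")
  expect_identical(parsed$biopsy_date, as.Date("2008-05-14"))
  expect_identical(parsed$dob, as.Date("1970-01-02"))
  expect_identical(parsed$sex, "F")
  expect_identical(parsed$glomeruli_total, 20L)
  expect_identical(parsed$glomeruli_global_sclerosis, 10L)
  expect_identical(parsed$glomeruli_segmental_sclerosis, 2L)
  expect_identical(parsed$crescents_pct, 5L)
  expect_identical(parsed$ifta_grade, "mild")
  expect_identical(parsed$if_iga, 3L)
  expect_identical(parsed$if_igg, 0L)
  expect_identical(parsed$if_kappa, 0L)
  expect_identical(parsed$em_effacement_pct, 30L)
  expect_identical(parsed$oxford_m, 1L)
  expect_identical(parsed$primary_dx_text, "IgA nephropathy")
  cls <- classify_reports(parsed)
  expect_identical(cls$primary_dx, "iga_nephropathy")
  expect_identical(cls$broad_group, "proliferative_gn")
})

test_that("round-trip: every generated report parses back to its ground truth", {
  run <- small_run()
  audit <- score_extraction(run$classified, run$truth)
  expect_identical(audit$overall_accuracy, 1)
  expect_true(all(audit$field_accuracy$accuracy == 1))
})

test_that("section order never changes extracted values", {
  run <- small_run()
  i <- which(run$truth$diagnostic)[1]
  truth1 <- run$truth[i, ]
  style1 <- run$styles[i, ]
  base <- classify_reports(parse_reports(render_report(truth1, style1)))
  for (k in 1:4) {
    style2 <- style1
    style2$section_order <- list(sample(canonical_section_order()))
    alt <- classify_reports(parse_reports(render_report(truth1, style2)))
    for (f in audit_fields()) {
      expect_identical(alt[[f]], base[[f]], info = f)
    }
  }
})

test_that("unseen phrasing degrades to missing, never to a wrong value", {
  doc <- sub("There are 10 globally sclerosed glomeruli.",
             "Sclerosed glomeruli (global): 10.", sample_report(), fixed = TRUE)
  parsed <- parse_report(doc)
  expect_true(is.na(parsed$glomeruli_global_sclerosis))
  expect_identical(parsed$glomeruli_total, 20L) # other fields untouched
  doc2 <- sub("IgA is 3\\+ in a granular pattern\\.",
              "Mesangial staining pattern consistent with IgA deposition.",
              sample_report())
  parsed2 <- parse_report(doc2)
  expect_true(is.na(parsed2$if_iga))
})

test_that("provenance offsets re-parse to the same value", {
  run <- small_run()
  prov <- attr(run$parsed, "provenance")
  counts <- prov[prov$field == "glomeruli_global_sclerosis" &
                   prov$status == "ok", ]
  counts <- counts[seq_len(min(nrow(counts), 15)), ]
  spec <- default_patterns()$fields$glomeruli_global_sclerosis
  for (j in seq_len(nrow(counts))) {
    doc <- run$documents$text[run$documents$doc_id == counts$doc_id[j]]
    slice <- stringr::str_sub(doc, counts$start[j], counts$end[j])
    expect_identical(as.character(extract_field(slice, spec)$value),
                     counts$value[j], info = counts$doc_id[j])
  }
})

test_that("nondiagnostic reports are flagged with no primary diagnosis", {
  run <- small_run()
  nd_truth <- !run$truth$diagnostic
  expect_identical(run$parsed$parse_status[nd_truth],
                   rep("nondiagnostic", sum(nd_truth)))
  expect_true(all(is.na(run$classified$primary_dx[nd_truth])))
})

test_that("legacy date style parses identically to ISO", {
  expect_identical(glomreg:::parse_report_date(c("2008-05-14", "14-May-2008")),
                   as.Date(c("2008-05-14", "2008-05-14")))
})
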