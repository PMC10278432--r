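Package: glomreg
Title: Construction of a Clinicopathologic Glomerular Disease Registry from
    Kidney Biopsy Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a population-based glomerular disease registry
    from semi-structured native kidney biopsy reports. Provides a seeded
    synthetic corpus generator that emulates the report format and cohort
    composition of a provincial biopsy registry, a pattern-based natural
    language processing engine that segments reports into canonical sections
    and extracts registry variables (glomerular counts, immunofluorescence
    panels, Oxford MEST-C and lupus nephritis indices, diagnoses) with
    per-field provenance, diagnosis canonicalization into broad disease
    groups, linkage to administrative tables under index-biopsy, covariate
    window and censoring rules, Kaplan-Meier and Cox proportional-hazards
    outcome analyses with small-cell suppression, and an audit harness that
    scores extraction fidelity against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
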