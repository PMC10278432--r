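---
title: "Building a glomerular-disease registry from biopsy reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a glomerular-disease registry from biopsy reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomreg)
```

## The problem

Glomerulonephritis (GN) comprises rare immune-mediated kidney diseases that
are diagnosed by kidney biopsy. A population-based registry of all biopsied
patients in a region supports epidemiology, risk stratification and trial
recruitment, but the source material — free-text pathology reports — is
semi-structured at best: the same six sections usually appear (patient
information, gross description, microscopic description, immunofluorescence,
electron microscopy, diagnosis), yet their order varies, some are absent,
and the same fact is phrased many ways ("There are 10 globally sclerosed
glomeruli", "The number of globally sclerotic glomeruli is 10", "Ten
glomeruli are globally sclerosed"). `glomreg` implements the full registry
construction: a pattern-based extraction engine, diagnosis canonicalization,
administrative linkage under explicit index/covariate/censoring rules,
survival analytics, and an audit harness — together with a synthetic report
corpus, because the real reports are protected health information and cannot
ship with the package.

## The synthetic universe

The generator is the package's study-condition definition, not a tuning
knob. Its default configuration (`registry_config()`) fixes:

* 2,263 diagnostic index episodes across 24 diagnosis codes; the eight
  common-GN counts (FSGS 115, secondary FSGS 127, IgA nephropathy 371,
  infection-related GN 111, lupus nephritis 132, membranous nephropathy 179,
  pauci-immune GN 203, minimal change disease 61 — 1,299 biopsies from 1,292
  individuals) and their per-era quotas, female counts, and
  kidney-failure/death event counts are taken from the published provincial
  cohort this fixture emulates.
* Multi-biopsy structure: 101 repeat biopsies with the same diagnosis, 20
  initial nondiagnostic biopsies followed by a diagnostic one, 15 later
  nondiagnostic biopsies, 22 patients with only a nondiagnostic biopsy
  (57 nondiagnostic reports in all), and 7 dual-diagnosis patients whose
  first episode is censored at the re-biopsy. Together: 2,421 reports from
  2,278 patients.
* Linkage failures: 175 patients absent from the coverage table. They are
  drawn from categories outside the two GN broad groups so that the
  post-linkage proliferative (883) and nonproliferative (562) biopsy totals
  and the 1,292 common-GN individuals are structural properties of the
  fixture rather than accidents of sampling.
* The study window (biopsies 2002-01-01 to 2019-12-31) and administrative
  follow-up end (2021-03-31).

The non-common category counts (diabetic nephropathy 220, tubulointerstitial
270, vascular 120, deposition 130, hereditary 60, other 18, plus 66
membranoproliferative-pattern and 80 fibrillary-pattern GN) are constrained
only by the broad-group totals above; their split across individual codes is
a package default, chosen once as clinically plausible for a native-biopsy
service and documented here as arbitrary. The same applies to all
microscopy value distributions (glomerular counts 10–35 per core,
immunofluorescence intensity tilts by diagnosis, effacement ranges): no
public source states these distributions, so they are round numbers a renal
pathologist would not find absurd — nothing downstream depends on them
beyond round-trip fidelity.

Event dates are drawn uniformly inside each episode's feasible window with
dialysis forced before death for patients reaching both endpoints, so the
injected per-diagnosis event *counts* are exact while event *times* are
synthetic; follow-up medians therefore do not (and are not meant to)
reproduce any published values. Dual-diagnosis patients take an era-1 slot
for their first diagnosis and an era-3 slot for the second, which keeps the
two dates ordered at the cost of a ±1 wobble in the per-era rows of the
affected categories.

All randomness flows from one root seed through `withr::with_seed`;
identical configuration and seed give byte-identical corpora.

## Rendering and the pattern library

Every extracted fact has at least three sentence templates, including a
number-word form for count fields ("Twenty-one glomeruli …", hyphenated
compounds, 0–99 — glomerular counts are two-digit numbers). Templates live
in `inst/extdata/report_templates.yaml` and the matching extraction patterns
in `inst/extdata/patterns.yaml`; adding a phrasing variant is a config
change, not a code change. Dates render ISO-8601 with a legacy
`DD-Mon-YYYY` style as noise; month names use the fixed English
abbreviations, never the locale. Style profiles also permute section order
(20% of documents), drop optional sections (gross 10%, EM 10%,
immunofluorescence 5%) and switch 25% of documents to number words. A fact
in a dropped section is removed from the ground truth as well, which is what
makes the round-trip contract ("every truth field is recoverable from the
document") testable.

The parser's design choices:

* **Section-restricted search with whole-document fallback.** Each field
  searches its declared section; if the section is undetected the whole
  document is searched — except the immunofluorescence panel, because
  antibody tokens such as "IgA" also occur in diagnosis text and a fallback
  would trade a missing value for a potentially wrong one.
* **Conflict over first-match-wins.** All matches of all patterns for a
  field are pooled; a single distinct value wins, disagreement yields
  `CONFLICT` with no value. The audit failure mode worth engineering against
  is the silently wrong value (a misread Oxford score), not the visible
  missing one.
* **Closed vocabularies** for grades (none/mild/moderate/severe) and
  staining intensities (0–3+, with "negative"/"no staining" mapping to 0);
  out-of-range lupus indices (activity > 24, chronicity > 12) are conflicts.
* **Provenance.** Every extracted value carries its pattern id and character
  offsets; the offset slice re-parses to the same value, which the tests use
  as a self-consistency oracle.

Unseen phrasing degrades monotonically: a novel sentence the library does
not know can only move a field from value to missing, never to a wrong
value, because every pattern anchors on its own distinctive lexical context.

## Cohort construction rules

* **Index biopsies.** Per patient in date order: nondiagnostic biopsies
  never define an episode; the first diagnostic biopsy is the index; repeat
  biopsies with the same diagnosis are ignored; a re-biopsy with a different
  diagnosis opens a second episode and censors the first at the re-biopsy
  date (such patients appear in both categories and are excluded from the
  survival models). A biopsy with an acute process on a chronic background
  carries the acute process as primary diagnosis.
* **Covariate windows.** Labs use the closed window ±3 calendar months
  around the index date, nearest result first, exact ties toward the
  pre-biopsy value. Medications use the half-open window (index,
  index + 6 months], matched on ATC prefixes (C09 ACEi/ARB, C10AA statins,
  C02/C03/C07/C08 other antihypertensives). The Charlson index uses claims
  in [index − 3 years, index), classic 17-condition weights, hierarchies
  keeping the severe member. Month windows are calendar months via date
  arithmetic, not fixed 91/182-day spans; both the widths and the ATC lists
  are arguments, since reasonable registries differ on the boundary
  conventions and no convention is ground truth.
* **uPCR conversion.** Urine protein-to-creatinine results are converted to
  albumin-to-creatinine before lab selection through a pluggable monotone
  log-linear map whose default is the identity; published conversion
  coefficients can be supplied by the caller. The package deliberately does
  not hard-code any particular published coefficient set.
* **Outcomes.** Kidney failure = first dialysis start or transplant after
  index; mortality from vital statistics. The endpoints are tracked
  independently (death censors the kidney-failure timeline; kidney failure
  does not end mortality follow-up), without competing-risk adjustment,
  matching the Kaplan-Meier/Cox design. Follow-up ends at the earliest of
  outcome, re-biopsy with a new diagnosis, coverage loss, or 2021-03-31;
  follow-up is measured in years as days/365.25. Patients with a
  kidney-replacement event on or before index are flagged prevalent and
  excluded from kidney-failure analyses (the mortality and kidney-failure
  models therefore use slightly different analysis sets). Early coverage
  termination and out-of-province emigration are indistinguishable in the
  administrative bundle and share the `coverage_loss` censor reason.

## Statistical layer

The descriptive table routes age through mean ± SD and every other
continuous variable through median (IQR) — per-variable configuration, not a
normality test, matching how such tables are conventionally built.
Percentages round half away from zero to one decimal. Small-cell
suppression (any count cell with 0 < n < 6 displays as "suppressed") is
applied after all aggregation and affects display strings only; the test
suite checks that suppressed cells keep their numeric estimates underneath.

Kaplan-Meier estimation and Cox fitting are delegated to the `survival`
package behind the module surface: `km_estimate()` returns a tidy
product-limit table (validated in the tests against an independent
brute-force life-table oracle, exhaustively over all event patterns of size
≤ 8 on a tie-rich time grid), and `cox_fit()` fits the published model form
(diagnosis indicators with IgA nephropathy as reference, age, sex with
female reference, eGFR, log urine ACR) with Efron tie handling, complete
cases only. Model quality is reported as AIC and Harrell's global
concordance index; where a published table labels this quantity "AUC"
without defining it, the global concordance interpretation is used and
labelled as such. Parameter recovery is tested by simulation: at n = 2,000
over 200 seeded replicates of a two-group exponential model with true hazard
ratio 2, the mean log-hazard-ratio bias stays below 0.05 and the 95%
confidence intervals cover the truth in at least 90% of replicates.

## Audit harness

The audit reproduces the development protocol of rule-based clinical NLP:
iterative scoring on disjoint samples of 10, 20 and 50 documents for pattern
tuning, then a stratified random audit of 100 documents with at least 5 from
every study year. Accuracy is exact match per field per document — the
strictest consistent reading — with missing-where-truth-has-a-value and
conflicts both counted as errors; per-field and per-document aggregations
are both emitted since either can be the unit of review. On the default
corpus the regression gate is accuracy exactly 1.0 for every field.

## What passing tests do and do not show

The synthetic corpus emulates the *structure* of real biopsy reports —
section layout, phrasing variation, number words, missing sections,
multi-biopsy patients, linkage failure — but its phrasing inventory is
finite and matched to the pattern library by construction. Perfect
round-trip accuracy on the fixture therefore validates the engine's
mechanics (segmentation, conflict handling, provenance, windows, censoring
logic), not performance on real-world reports, which would contain phrasing
no fixed inventory anticipates; on real data the expected behaviour is
degradation to missing values surfaced by the audit harness, followed by
pattern-library extension. Likewise the survival results on the fixture
reflect injected event counts with synthetic event times, so hazard-ratio
magnitudes are not substantive findings.

## Problem sizes

The default corpus (2,421 reports) generates, renders and parses in well
under a minute on a single core; the test suite, including the exhaustive
small-sample survival sweep and the 200-replicate Cox recovery study, runs
in about half a minute. These sizes were chosen so the full pipeline is
exercised end-to-end at the fixture's natural scale on any laptop.
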