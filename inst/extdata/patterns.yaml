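# Pattern library for the report parser. One entry per extracted field:
# the target section, the value type (selects the post-processor), and an
# ordered list of patterns, each with exactly one capture slot. Placeholders
# are expanded at load time:
#   {{COUNT}} -> capture matching a digit string or an English number word 0-99
#   {{DATE}}  -> capture matching ISO-8601 or DD-Mon-YYYY dates
# Patterns are matched case-insensitively within the declared section,
# falling back to the whole document when the section is absent (the
# immunofluorescence panel never falls back; antibody tokens also occur in
# diagnosis text). Disagreeing matches yield CONFLICT, not first-match-wins.
sections:
  patient_information: ["patient information", "patient data", "demographics"]
  gross_description: ["gross description", "macroscopic description", "gross examination"]
  microscopic_description: ["microscopic description", "light microscopy", "microscopy"]
  immunofluorescence: ["immunofluorescence microscopy", "immunofluorescence"]
  electron_microscopy: ["electron microscopy", "ultrastructural examination"]
  diagnosis: ["final diagnosis", "pathologic diagnosis", "diagnosis"]

fields:
  phin:
    section: patient_information
    type: code
    patterns:
      - id: phin_labelled
        regex: "(?:PHIN|personal health identification number|health id)[:\\s]+(\\d{9})"
  biopsy_date:
    section: patient_information
    type: date
    patterns:
      - id: biopsy_date_labelled
        regex: "(?:date of biopsy|biopsy date|specimen collected on)[:\\s]+{{DATE}}"
  dob:
    section: patient_information
    type: date
    patterns:
      - id: dob_labelled
        regex: "(?:date of birth|dob|born)[:\\s]+{{DATE}}"
  sex:
    section: patient_information
    type: sex
    patterns:
      - id: sex_labelled
        regex: "(?:sex|gender)[:\\s]+(female|male|f|m)\\b"
  glomeruli_total:
    section: microscopic_description
    type: count
    patterns:
      - id: total_contains
        regex: "the biopsy contains {{COUNT}} glomeruli"
      - id: total_total_of
        regex: "a total of {{COUNT}} glomeruli (?:are|is) present"
      - id: total_identified
        regex: "{{COUNT}} glomeruli are identified"
  glomeruli_global_sclerosis:
    section: microscopic_description
    type: count
    patterns:
      - id: global_there_are
        regex: "there (?:are|is) {{COUNT}} globally scleros(?:ed|tic) glomeruli"
      - id: global_number_is
        regex: "the number of globally sclero(?:tic|sed) glomeruli is {{COUNT}}"
      - id: global_subject_first
        regex: "{{COUNT}} glomeruli are globally scleros(?:ed|tic)"
  glomeruli_segmental_sclerosis:
    section: microscopic_description
    type: count
    patterns:
      - id: segmental_there_are
        regex: "there (?:are|is) {{COUNT}} segmentally scleros(?:ed|tic) glomeruli"
      - id: segmental_number_is
        regex: "the number of segmentally sclero(?:tic|sed) glomeruli is {{COUNT}}"
      - id: segmental_subject_first
        regex: "{{COUNT}} glomeruli show segmental sclerosis"
  crescents_pct:
    section: microscopic_description
    type: percent
    patterns:
      - id: crescents_present_in
        regex: "crescents are present in (\\d{1,3})\\s?(?:%|percent)"
      - id: crescents_involve
        regex: "crescents involve (\\d{1,3})\\s?(?:%|percent)"
      - id: crescents_none
        regex: "(no) crescents are identified"
  ifta_grade:
    section: microscopic_description
    type: grade
    patterns:
      - id: ifta_there_is
        regex: "there is (no|mild|moderate|severe) interstitial fibrosis and tubular atrophy"
      - id: ifta_labelled
        regex: "interstitial fibrosis and tubular atrophy[:\\s]+(none|mild|moderate|severe)"
      - id: ifta_short
        regex: "IFTA is (none|mild|moderate|severe)"
  em_effacement_pct:
    section: electron_microscopy
    type: percent
    patterns:
      - id: effacement_involving
        regex: "effacement involving (\\d{1,3})\\s?(?:%|percent)"
      - id: effacement_percent_first
        regex: "(\\d{1,3})\\s?(?:%|percent) foot process effacement"
      - id: effacement_labelled
        regex: "foot process effacement[:\\s]+(\\d{1,3})\\s?(?:%|percent)"
  ln_activity:
    section: diagnosis
    type: count
    range: [0, 24]
    patterns:
      - id: activity_index
        regex: "activity index(?: of)?[:\\s]+{{COUNT}}"
  ln_chronicity:
    section: diagnosis
    type: count
    range: [0, 12]
    patterns:
      - id: chronicity_index
        regex: "chronicity index(?: of)?[:\\s]+{{COUNT}}"

if_panel:
  section: immunofluorescence
  antibodies: ["IgG", "IgA", "IgM", "C3", "C1q", "kappa", "lambda"]
  intensity_regex: "\\b{{AB}}\\b\\s*(?:is|:|shows)?\\s*([0-3])\\+"
  negative_regex: "\\b{{AB}}\\b\\s*(?:is|:|shows)?\\s*(?:negative|no staining)"

oxford:
  section: diagnosis
  regex: "(?:oxford(?: score| classification)?|MEST-?C)[:\\s]*M\\s?([01])[,\\s]*E\\s?([01])[,\\s]*S\\s?([01])[,\\s]*T\\s?([012])[,\\s]*C\\s?([012])"

diagnosis:
  section: diagnosis
  nondiagnostic_regex: "inadequate sample|insufficient for diagnosis|nondiagnostic|normal kidney tissue"
  secondary_regexes:
    - "on a background of ([^.\\n]+)"
    - "secondary diagnosis[:\\s]+([^.\\n]+)"
    - "associated with underlying ([^.\\n]+)"
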