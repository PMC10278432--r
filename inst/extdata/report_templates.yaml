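# Sentence templates used by the report renderer. Each extracted field has
# at least three phrasings; count-valued fields render the value as English
# number words when the document's number style says so. `{value}` is the
# substitution slot. Adding a variant here (and a matching pattern in
# patterns.yaml) requires no code change.
fields:
  phin:
    section: patient_information
    templates:
      - "PHIN: {value}"
      - "Personal health identification number: {value}"
      - "Health ID {value}"
  biopsy_date:
    section: patient_information
    templates:
      - "Date of biopsy: {value}"
      - "Biopsy date: {value}"
      - "Specimen collected on {value}"
  dob:
    section: patient_information
    templates:
      - "Date of birth: {value}"
      - "DOB: {value}"
      - "Born {value}"
  sex:
    section: patient_information
    templates:
      - "Sex: {value}"
      - "Sex: {value_full}"
      - "Gender: {value_lower}"
  glomeruli_total:
    section: microscopic_description
    templates:
      - "The biopsy contains {value} glomeruli."
      - "A total of {value} glomeruli are present for evaluation."
      - "{Value} glomeruli are identified in the sample."
  glomeruli_global_sclerosis:
    section: microscopic_description
    templates:
      - "There are {value} globally sclerosed glomeruli."
      - "The number of globally sclerotic glomeruli is {value}."
      - "{Value} glomeruli are globally sclerosed."
  glomeruli_segmental_sclerosis:
    section: microscopic_description
    templates:
      - "There are {value} segmentally sclerosed glomeruli."
      - "The number of segmentally sclerotic glomeruli is {value}."
      - "{Value} glomeruli show segmental sclerosis."
  crescents_pct:
    section: microscopic_description
    templates:
      - "Cellular crescents are present in {value}% of glomeruli."
      - "Crescents involve {value} percent of glomeruli."
      - "No crescents are identified."   # zero only; nonzero falls back to variant 1
  ifta_grade:
    section: microscopic_description
    templates:
      - "There is {value_no} interstitial fibrosis and tubular atrophy."
      - "Interstitial fibrosis and tubular atrophy: {value}."
      - "IFTA is {value}."
  em_effacement_pct:
    section: electron_microscopy
    templates:
      - "Electron microscopy demonstrates foot process effacement involving {value}% of the capillary surface."
      - "There is {value} percent foot process effacement."
      - "Foot process effacement: {value}%."
  if_positive:
    section: immunofluorescence
    templates:
      - "{ab} is {value}+ in a granular pattern."
      - "{ab}: {value}+."
      - "{ab} shows {value}+ staining."
  if_negative:
    section: immunofluorescence
    templates:
      - "{ab} is negative."
      - "{ab}: negative."
      - "{ab} shows no staining."
  oxford:
    section: diagnosis
    templates:
      - "Oxford score M{m} E{e} S{s} T{t} C{c}."
      - "MEST-C: M{m}E{e}S{s}T{t}C{c}."
      - "Oxford classification: M{m}, E{e}, S{s}, T{t}, C{c}."
  ln_indices:
    section: diagnosis
    templates:
      - "Activity index {a}/24, chronicity index {c}/12."
      - "Activity index of {a_words} out of 24 and chronicity index of {c_words} out of 12."
      - "NIH activity index: {a}; chronicity index: {c}."
  dx_primary:
    section: diagnosis
    templates:
      - "{label}."
      - "Primary diagnosis: {label}."
      - "Final diagnosis: {label}."
  dx_secondary:
    section: diagnosis
    templates:
      - "Seen on a background of {label}."
      - "Secondary diagnosis: {label}."
      - "Associated with underlying {label}."
  nondiagnostic:
    section: diagnosis
    templates:
      - "Inadequate sample; no definitive diagnosis can be rendered."
      - "The specimen is insufficient for diagnosis."
      - "Normal kidney tissue; nondiagnostic sample."
  gross_filler:
    section: gross_description
    templates:
      - "The specimen consists of {k} cores of tan-brown tissue measuring up to {len} cm."
      - "Received {k} cores of pale tan tissue, the largest {len} cm in length."
      - "{K} needle cores of renal parenchyma are submitted, up to {len} cm."
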