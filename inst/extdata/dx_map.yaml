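# Diagnosis canonicalization and broad-group assignment.
# Each code carries a display label, one of the eight broad disease groups,
# a common-GN flag (the eight most frequent glomerular diseases), and a
# case-insensitive synonym list used longest-match-first.
# Proliferative vs nonproliferative membership follows the standard
# clinicopathologic classification and is editable here without code changes.
codes:
  fsgs:
    label: "Focal segmental glomerulosclerosis"
    group: nonproliferative_gn
    common_gn: true
    synonyms:
      - "focal segmental glomerulosclerosis"
      - "primary focal segmental glomerulosclerosis"
      - "FSGS"
  secondary_fsgs:
    label: "Secondary focal segmental glomerulosclerosis"
    group: nonproliferative_gn
    common_gn: true
    synonyms:
      - "secondary focal segmental glomerulosclerosis"
      - "secondary FSGS"
      - "adaptive focal segmental glomerulosclerosis"
  iga_nephropathy:
    label: "IgA nephropathy"
    group: proliferative_gn
    common_gn: true
    synonyms:
      - "IgA nephropathy"
      - "immunoglobulin A nephropathy"
      - "IgA glomerulonephritis"
      - "Berger disease"
  infection_related_gn:
    label: "Infection-related glomerulonephritis"
    group: proliferative_gn
    common_gn: true
    synonyms:
      - "infection-related glomerulonephritis"
      - "infection related glomerulonephritis"
      - "postinfectious glomerulonephritis"
      - "post-infectious glomerulonephritis"
      - "infection-related GN"
  lupus_nephritis:
    label: "Lupus nephritis"
    group: proliferative_gn
    common_gn: true
    synonyms:
      - "lupus nephritis"
      - "systemic lupus erythematosus nephritis"
  membranous_nephropathy:
    label: "Membranous nephropathy"
    group: nonproliferative_gn
    common_gn: true
    synonyms:
      - "membranous nephropathy"
      - "membranous glomerulonephritis"
      - "membranous glomerulopathy"
  pauci_immune_gn:
    label: "Pauci-immune glomerulonephritis"
    group: proliferative_gn
    common_gn: true
    synonyms:
      - "pauci-immune glomerulonephritis"
      - "pauci immune glomerulonephritis"
      - "pauci-immune GN"
      - "crescentic ANCA-associated glomerulonephritis"
      - "ANCA-associated glomerulonephritis"
      - "ANCA-associated vasculitis"
  minimal_change_disease:
    label: "Minimal change disease"
    group: nonproliferative_gn
    common_gn: true
    synonyms:
      - "minimal change disease"
      - "minimal change nephropathy"
      - "nil disease"
  diabetic_nephropathy:
    label: "Diabetic nephropathy"
    group: diabetic_nephropathy
    common_gn: false
    synonyms:
      - "diabetic nephropathy"
      - "diabetic glomerulosclerosis"
      - "nodular diabetic glomerulosclerosis"
      - "diabetic kidney disease"
  acute_tubular_injury:
    label: "Acute tubular injury"
    group: tubulointerstitial
    common_gn: false
    synonyms:
      - "acute tubular injury"
      - "acute tubular necrosis"
  acute_interstitial_nephritis:
    label: "Acute interstitial nephritis"
    group: tubulointerstitial
    common_gn: false
    synonyms:
      - "acute interstitial nephritis"
  chronic_interstitial_nephritis:
    label: "Chronic interstitial nephritis"
    group: tubulointerstitial
    common_gn: false
    synonyms:
      - "chronic interstitial nephritis"
      - "chronic tubulointerstitial nephritis"
  light_chain_cast_nephropathy:
    label: "Light chain cast nephropathy"
    group: tubulointerstitial
    common_gn: false
    synonyms:
      - "light chain cast nephropathy"
      - "myeloma cast nephropathy"
  light_chain_proximal_tubulopathy:
    label: "Light chain proximal tubulopathy"
    group: tubulointerstitial
    common_gn: false
    synonyms:
      - "light chain proximal tubulopathy"
  thrombotic_microangiopathy:
    label: "Thrombotic microangiopathy"
    group: vascular
    common_gn: false
    synonyms:
      - "thrombotic microangiopathy"
  ischemic_hypertensive:
    label: "Ischemic glomerulopathy/hypertensive kidney disease"
    group: vascular
    common_gn: false
    synonyms:
      - "ischemic glomerulopathy/hypertensive kidney disease"
      - "ischemic glomerulopathy"
      - "hypertensive kidney disease"
      - "hypertensive nephrosclerosis"
      - "arterionephrosclerosis"
  al_amyloidosis:
    label: "AL amyloidosis"
    group: deposition
    common_gn: false
    synonyms:
      - "AL amyloidosis"
      - "amyloidosis, AL type"
      - "light chain amyloidosis"
  monoclonal_ig_deposition:
    label: "Monoclonal immunoglobulin deposition disease"
    group: deposition
    common_gn: false
    synonyms:
      - "monoclonal immunoglobulin deposition disease"
      - "light chain deposition disease"
  alport_hereditary_nephritis:
    label: "Alport syndrome/hereditary nephritis"
    group: hereditary
    common_gn: false
    synonyms:
      - "Alport syndrome/hereditary nephritis"
      - "Alport syndrome"
      - "hereditary nephritis"
  fabry_disease:
    label: "Fabry disease"
    group: hereditary
    common_gn: false
    synonyms:
      - "Fabry disease"
  thin_basement_membrane:
    label: "Thin basement membrane nephropathy"
    group: hereditary
    common_gn: false
    synonyms:
      - "thin basement membrane nephropathy"
      - "thin basement membrane disease"
  mpgn:
    label: "Membranoproliferative glomerulonephritis"
    group: proliferative_gn
    common_gn: false
    synonyms:
      - "membranoproliferative glomerulonephritis"
      - "C3 glomerulopathy"
      - "C3 glomerulonephritis"
  fibrillary_gn:
    label: "Fibrillary glomerulonephritis"
    group: nonproliferative_gn
    common_gn: false
    synonyms:
      - "fibrillary glomerulonephritis"
      - "immunotactoid glomerulopathy"
  other:
    label: "Other kidney disease"
    group: unclassified
    common_gn: false
    synonyms:
      - "other kidney disease"
  nondiagnostic:
    label: "Nondiagnostic"
    group: unclassified
    common_gn: false
    synonyms:
      - "nondiagnostic"
      - "inadequate sample"
      - "normal kidney tissue"
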