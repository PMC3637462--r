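tests:
  gFOBT:
    name: gFOBT
    sens_low_adenoma: 0.11
    sens_inthigh_adenoma: 0.11
    sens_crc: 0.36
    specificity: 0.97
    reach: whole_colon
    uptake: 0.53
  FIT:
    name: FIT
    sens_low_adenoma: 0.21
    sens_inthigh_adenoma: 0.21
    sens_crc: 0.71
    specificity: 0.95
    reach: whole_colon
    uptake: 0.53
  FSIG:
    name: FSIG
    sens_low_adenoma: 0.65
    sens_inthigh_adenoma: 0.74
    sens_crc: 0.9
    specificity: 0.92
    reach: distal_only
    uptake: 0.39
sensitivity_bounds:
  gFOBT:
    uptake:
    - 0.32
    - 0.7
    sens_adenoma:
    - 0.1
    - 0.12
    sens_crc:
    - 0.31
    - 0.42
    specificity:
    - 0.96
    - 0.98
  FIT:
    uptake:
    - 0.32
    - 0.7
    sens_adenoma:
    - 0.19
    - 0.22
    sens_crc:
    - 0.67
    - 0.75
    specificity:
    - 0.94
    - 0.96
  FSIG:
    uptake:
    - 0.24
    - 0.67
    sens_low_adenoma:
    - 0.6
    - 0.7
    sens_inthigh_adenoma:
    - 0.68
    - 0.78
    sens_crc:
    - 0.85
    - 0.95
    specificity:
    - 0.9
    - 0.95
pathway:
  colonoscopy_compliance: 0.86
  ctc_fraction_of_workups: 0.115
  col_sens_low: 0.77
  col_sens_inthigh: 0.98
  col_sens_crc: 0.98
  col_spec: 0.97
  ctc_sens_low: 0.53
  ctc_sens_inthigh: 0.85
  ctc_sens_crc: 0.85
  ctc_spec: 0.86
harms:
  fsig_perf: 2.0e-05
  fsig_perf_death: 0.06452
  fsig_bleed: 0.00029
  col_perf_polyp: 0.00216
  col_perf_nopolyp: 0.00107
  col_perf_death: 0.05195
  col_bleed: 0.00379
surveillance:
  interval_years_intermediate: 3
  interval_years_high: 1
  high_risk_fraction: 0.29
  inthigh_yield: 0.06
  applies_to: AdenomaIntHighRisk
distal_fraction: 0.6
weak_positive_fraction: 0.0
adenomas_per_person: 1.9
screen_detect_cure:
  I: 0.95
  II: 0.8
  III: 0.6
  IV: 0.2
crc_workup_fractions:
  pet: 0.1
  mri: 0.36
  ct: 1.0
  tus: 0.052
  preop_rt: 0.23
  resections: 0.91
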