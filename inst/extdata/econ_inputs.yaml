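params:
- name: utility_pf
  group: utility
  value: 0.84
  dist: beta
  low: 0.672
  high: 0.883
- name: utility_pp
  group: utility
  value: 0.473
  dist: beta
  low: 0.166
  high: 0.568
- name: cost_atezolizumab_per10mg
  group: unit_cost
  value: 77.46
  dist: gamma
  low: 77.01
  high: 77.76
- name: cost_etoposide_per10mg
  group: unit_cost
  value: 0.66
  dist: gamma
  low: 0.56
  high: 0.74
- name: cost_carboplatin_per50mg
  group: unit_cost
  value: 3.09
  dist: gamma
  low: 2.89
  high: 3.25
- name: cost_topotecan_per0.1mg
  group: unit_cost
  value: 0.94
  dist: gamma
  low: 0.87
  high: 1.01
- name: cost_cyclophosphamide_per100mg
  group: unit_cost
  value: 3.91
  dist: gamma
  low: 3.31
  high: 4.54
- name: cost_doxorubicin_per10mg
  group: unit_cost
  value: 3.08
  dist: gamma
  low: 2.89
  high: 3.73
- name: cost_vincristine_per1mg
  group: unit_cost
  value: 4.88
  dist: gamma
  low: 4.79
  high: 5.0
- name: cost_supportive_care
  group: cost
  value: 478.0
  dist: gamma
  low: 359.0
  high: 597.0
- name: cost_death
  group: cost
  value: 9433.0
  dist: gamma
  low: 7075.0
  high: 11791.0
- name: cost_admin_first
  group: cost
  value: 144.72
  dist: gamma
  low: 115.78
  high: 173.66
- name: cost_admin_additional
  group: cost
  value: 31.68
  dist: gamma
  low: 25.34
  high: 38.02
- name: cost_ae_neutropenia
  group: ae_cost
  value: 17181.0
  dist: gamma
  low: 13745.0
  high: 20617.0
- name: cost_ae_anemia
  group: ae_cost
  value: 20260.0
  dist: gamma
  low: 16208.0
  high: 24312.0
- name: cost_ae_neutrophil_count_decreased
  group: ae_cost
  value: 17181.0
  dist: gamma
  low: 13745.0
  high: 20617.0
- name: cost_ae_thrombocytopenia
  group: ae_cost
  value: 22698.0
  dist: gamma
  low: 20289.0
  high: 25377.0
- name: cost_ae_leukopenia
  group: ae_cost
  value: 17181.0
  dist: gamma
  low: 13745.0
  high: 20617.0
- name: risk_ac_neutropenia
  group: ae_risk
  value: 0.23
  dist: beta
  low: 0.19
  high: 0.28
- name: risk_ac_anemia
  group: ae_risk
  value: 0.14
  dist: beta
  low: 0.11
  high: 0.17
- name: risk_ac_neutrophil_count_decreased
  group: ae_risk
  value: 0.14
  dist: beta
  low: 0.11
  high: 0.17
- name: risk_ac_thrombocytopenia
  group: ae_risk
  value: 0.1
  dist: beta
  low: 0.08
  high: 0.12
- name: risk_ac_leukopenia
  group: ae_risk
  value: 0.05
  dist: beta
  low: 0.04
  high: 0.06
- name: risk_c_neutropenia
  group: ae_risk
  value: 0.25
  dist: beta
  low: 0.2
  high: 0.29
- name: risk_c_anemia
  group: ae_risk
  value: 0.12
  dist: beta
  low: 0.1
  high: 0.15
- name: risk_c_neutrophil_count_decreased
  group: ae_risk
  value: 0.17
  dist: beta
  low: 0.13
  high: 0.2
- name: risk_c_thrombocytopenia
  group: ae_risk
  value: 0.08
  dist: beta
  low: 0.06
  high: 0.09
- name: risk_c_leukopenia
  group: ae_risk
  value: 0.04
  dist: beta
  low: 0.03
  high: 0.05
- name: discount_rate
  group: rate
  value: 0.03
  dist: fixed
  low: 0.0
  high: 0.05
- name: disutility_neutropenia
  group: ae_disutility
  value: -0.09
  dist: beta
  low: -0.122
  high: -0.062
- name: disutility_anemia
  group: ae_disutility
  value: -0.09
  dist: beta
  low: -0.133
  high: -0.055
- name: disutility_neutrophil_count_decreased
  group: ae_disutility
  value: -0.09
  dist: beta
  low: -0.122
  high: -0.062
- name: disutility_thrombocytopenia
  group: ae_disutility
  value: -0.108
  dist: beta
  low: -0.128
  high: -0.089
- name: disutility_leukopenia
  group: ae_disutility
  value: -0.09
  dist: beta
  low: -0.122
  high: -0.062
- name: duration_neutropenia
  group: ae_duration
  value: 2.0
  dist: normal
  low: 2.0
  high: 2.0
- name: duration_anemia
  group: ae_duration
  value: 21.0
  dist: normal
  low: 17.0
  high: 25.0
- name: duration_neutrophil_count_decreased
  group: ae_duration
  value: 4.0
  dist: normal
  low: 3.0
  high: 5.0
- name: duration_thrombocytopenia
  group: ae_duration
  value: 24.0
  dist: normal
  low: 19.0
  high: 28.0
- name: duration_leukopenia
  group: ae_duration
  value: 2.0
  dist: normal
  low: 2.0
  high: 2.0
constants:
  patient:
    weight_kg: 70.0
    bsa_m2: 1.86
    crcl_ml_min: 70.0
  second_line:
    uptake:
      intervention:
        topotecan: 0.403
        cav: 0.154
      control:
        topotecan: 0.436
        cav: 0.228
    n_cycles: 4.0
  regimens:
    chemo_cycles: 4.0
    etoposide_days: 3.0
    topotecan_days: 5.0
    atezolizumab_mg: 1200.0
    carboplatin_auc: 5.0
    etoposide_mg_m2: 100.0
    topotecan_mg_m2: 1.5
    cyclophosphamide_mg_m2: 1000.0
    doxorubicin_mg_m2: 45.0
    vincristine_mg: 2.0
  ae_events:
  - neutropenia
  - anemia
  - neutrophil_count_decreased
  - thrombocytopenia
  - leukopenia
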