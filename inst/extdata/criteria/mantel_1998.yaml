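# Mantel 1998 organ-dysfunction criteria.
set_id: mantel_1998
label: Mantel organ-dysfunction criteria, 1998
combinator: any_one
predicates:
  - predicate_id: mantel_pulmonary_oedema
    category: clinical
    expression: {flag: pulmonary_oedema}
  - predicate_id: mantel_cardiac_arrest
    category: clinical
    expression: {flag: cardiac_arrest}
  - predicate_id: mantel_intubation_ventilation
    category: management
    expression: {flag: intubation_ventilation_gt_60min_non_anaesthetic}
  - predicate_id: mantel_spo2_lt_90
    category: laboratory
    expression: {measurement: spo2_pct_sustained_60min, cmp: '<', value: 90}
  - predicate_id: mantel_pao2_fio2_le_300
    category: laboratory
    expression: {measurement: pao2_fio2_mmHg, cmp: '<=', value: 300}
  - predicate_id: mantel_oliguria
    category: clinical
    expression: {flag: oliguria_nonresponsive}
  - predicate_id: mantel_urea_gt_15
    category: laboratory
    expression: {measurement: urea_mmol_L, cmp: '>', value: 15}
  # > 400 umol/L, canonical mg/dL: 400 / 88.4
  - predicate_id: mantel_creatinine_gt_400umol
    category: laboratory
    expression: {measurement: creatinine_mg_dL, cmp: '>', value: 4.525}
  - predicate_id: mantel_platelet_transfusion
    category: management
    expression: {flag: platelet_transfusion}
  - predicate_id: mantel_transfusion_ge_5
    category: management
    expression: {measurement: transfusion_units, cmp: '>=', value: 5}
  - predicate_id: mantel_jaundice_preeclampsia
    category: clinical
    expression:
      any_of:
        - {flag: jaundice_with_preeclampsia}
        - all_of:
            - {flag: jaundice}
            - {flag: preeclampsia}
  - predicate_id: mantel_coma_gt_12h
    category: clinical
    expression: {flag: loss_of_consciousness_gt_12h}
  - predicate_id: mantel_intracranial_haemorrhage
    category: clinical
    expression: {flag: cerebrovascular_accident}
  - predicate_id: mantel_sepsis_icu
    category: clinical
    expression: {flag: sepsis_icu_admission}
  - predicate_id: mantel_diabetic_ketoacidosis
    category: clinical
    expression: {flag: diabetic_ketoacidosis}
  - predicate_id: mantel_thyroid_crisis
    category: clinical
    expression: {flag: thyroid_crisis}
  - predicate_id: mantel_emergency_hysterectomy
    category: management
    expression: {flag: hysterectomy}
  - predicate_id: mantel_anaesthesia_complication
    category: clinical
    expression: {flag: anaesthesia_complication}
  - predicate_id: mantel_icu_admission
    category: management
    expression: {flag: icu_admission}
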