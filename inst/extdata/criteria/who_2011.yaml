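# WHO 2011 near-miss tool: 25 severity indicators
# (12 clinical, 7 laboratory, 6 management), any one positive => near miss.
set_id: who_2011
label: WHO near-miss criteria, 2011
combinator: any_one
predicates:
  # clinical (12)
  - predicate_id: who_clin_acute_cyanosis
    category: clinical
    expression: {flag: acute_cyanosis}
  - predicate_id: who_clin_gasping
    category: clinical
    expression: {flag: gasping}
  - predicate_id: who_clin_respiratory_rate
    category: clinical
    expression: {measurement: respiratory_rate_per_min, outside: [6, 40]}
  - predicate_id: who_clin_shock
    category: clinical
    expression: {flag: shock}
  - predicate_id: who_clin_cardiac_arrest
    category: clinical
    expression: {flag: cardiac_arrest}
  - predicate_id: who_clin_oliguria
    category: clinical
    expression: {flag: oliguria_nonresponsive}
  - predicate_id: who_clin_clotting_failure
    category: clinical
    expression: {flag: failure_to_form_clots}
  - predicate_id: who_clin_loss_of_consciousness
    category: clinical
    expression: {flag: loss_of_consciousness_gt_12h}
  - predicate_id: who_clin_stroke
    category: clinical
    expression: {flag: stroke}
  - predicate_id: who_clin_uncontrollable_fits
    category: clinical
    expression:
      any_of:
        - {flag: uncontrollable_fits}
        - {flag: status_epilepticus}
  - predicate_id: who_clin_total_paralysis
    category: clinical
    expression: {flag: total_paralysis}
  - predicate_id: who_clin_jaundice_preeclampsia
    category: clinical
    expression:
      any_of:
        - {flag: jaundice_with_preeclampsia}
        - all_of:
            - {flag: jaundice}
            - {flag: preeclampsia}
  # laboratory (7)
  - predicate_id: who_lab_spo2_lt_90
    category: laboratory
    expression: {measurement: spo2_pct_sustained_60min, cmp: '<', value: 90}
  - predicate_id: who_lab_ph_lt_7_1
    category: laboratory
    expression: {measurement: ph, cmp: '<', value: 7.1}
  - predicate_id: who_lab_pao2_fio2_lt_200
    category: laboratory
    expression: {measurement: pao2_fio2_mmHg, cmp: '<', value: 200}
  - predicate_id: who_lab_lactate_gt_5
    category: laboratory
    expression: {measurement: lactate_mmol_L, cmp: '>', value: 5}
  - predicate_id: who_lab_creatinine_ge_3_5
    category: laboratory
    expression: {measurement: creatinine_mg_dL, cmp: '>=', value: 3.5}
  - predicate_id: who_lab_thrombocytopenia_le_50000
    category: laboratory
    expression: {measurement: platelet_count_per_mm3, cmp: '<=', value: 50000}
  - predicate_id: who_lab_bilirubin_gt_6
    category: laboratory
    expression: {measurement: bilirubin_mg_dL, cmp: '>', value: 6.0}
  # management (6)
  - predicate_id: who_mgmt_vasoactive_drugs
    category: management
    expression: {flag: vasoactive_drug_use}
  - predicate_id: who_mgmt_intubation_ventilation
    category: management
    expression: {flag: intubation_ventilation_gt_60min_non_anaesthetic}
  - predicate_id: who_mgmt_hysterectomy
    category: management
    expression: {flag: hysterectomy}
  - predicate_id: who_mgmt_dialysis
    category: management
    expression: {flag: dialysis_acute_renal_failure}
  - predicate_id: who_mgmt_transfusion_ge_5
    category: management
    expression: {measurement: transfusion_units, cmp: '>=', value: 5}
  - predicate_id: who_mgmt_cpr
    category: management
    expression: {flag: cpr}
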