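# Indian national consensus criteria, 2014.
# Combination rule: positive when at least one criterion is met in EACH of
# the clinical_finding, investigation and intervention sections, OR any
# single criterion signifying cardiorespiratory collapse.
# The full national roster (>100 indicator variables) is not public in a
# machine-readable form; this default partitions the WHO severity
# indicators into the three sections (clinical flags -> clinical_finding,
# laboratory thresholds -> investigation, management flags -> intervention)
# with a four-item collapse shortcut. Users can override with their own
# YAML in the same grammar.
set_id: indian_2014
label: Indian national consensus criteria, 2014
combinator: indian_sections
predicates:
  # clinical findings
  - predicate_id: in_clin_acute_cyanosis
    category: clinical
    indian_section: clinical_finding
    expression: {flag: acute_cyanosis}
  - predicate_id: in_clin_gasping
    category: clinical
    indian_section: clinical_finding
    expression: {flag: gasping}
  - predicate_id: in_clin_respiratory_rate
    category: clinical
    indian_section: clinical_finding
    expression: {measurement: respiratory_rate_per_min, outside: [6, 40]}
  - predicate_id: in_clin_shock
    category: clinical
    indian_section: clinical_finding
    expression: {flag: shock}
  - predicate_id: in_clin_cardiac_arrest
    category: clinical
    indian_section: clinical_finding
    expression: {flag: cardiac_arrest}
  - predicate_id: in_clin_oliguria
    category: clinical
    indian_section: clinical_finding
    expression: {flag: oliguria_nonresponsive}
  - predicate_id: in_clin_clotting_failure
    category: clinical
    indian_section: clinical_finding
    expression: {flag: failure_to_form_clots}
  - predicate_id: in_clin_loss_of_consciousness
    category: clinical
    indian_section: clinical_finding
    expression: {flag: loss_of_consciousness_gt_12h}
  - predicate_id: in_clin_stroke
    category: clinical
    indian_section: clinical_finding
    expression: {flag: stroke}
  - predicate_id: in_clin_fits
    category: clinical
    indian_section: clinical_finding
    expression:
      any_of:
        - {flag: uncontrollable_fits}
        - {flag: status_epilepticus}
  - predicate_id: in_clin_total_paralysis
    category: clinical
    indian_section: clinical_finding
    expression: {flag: total_paralysis}
  - predicate_id: in_clin_jaundice_preeclampsia
    category: clinical
    indian_section: clinical_finding
    expression:
      any_of:
        - {flag: jaundice_with_preeclampsia}
        - all_of:
            - {flag: jaundice}
            - {flag: preeclampsia}
  # investigations
  - predicate_id: in_inv_spo2_lt_90
    category: laboratory
    indian_section: investigation
    expression: {measurement: spo2_pct_sustained_60min, cmp: '<', value: 90}
  - predicate_id: in_inv_ph_lt_7_1
    category: laboratory
    indian_section: investigation
    expression: {measurement: ph, cmp: '<', value: 7.1}
  - predicate_id: in_inv_pao2_fio2_lt_200
    category: laboratory
    indian_section: investigation
    expression: {measurement: pao2_fio2_mmHg, cmp: '<', value: 200}
  - predicate_id: in_inv_lactate_gt_5
    category: laboratory
    indian_section: investigation
    expression: {measurement: lactate_mmol_L, cmp: '>', value: 5}
  - predicate_id: in_inv_creatinine_ge_3_5
    category: laboratory
    indian_section: investigation
    expression: {measurement: creatinine_mg_dL, cmp: '>=', value: 3.5}
  - predicate_id: in_inv_thrombocytopenia_le_50000
    category: laboratory
    indian_section: investigation
    expression: {measurement: platelet_count_per_mm3, cmp: '<=', value: 50000}
  - predicate_id: in_inv_bilirubin_gt_6
    category: laboratory
    indian_section: investigation
    expression: {measurement: bilirubin_mg_dL, cmp: '>', value: 6.0}
  # interventions
  - predicate_id: in_int_vasoactive_drugs
    category: management
    indian_section: intervention
    expression: {flag: vasoactive_drug_use}
  - predicate_id: in_int_intubation_ventilation
    category: management
    indian_section: intervention
    expression: {flag: intubation_ventilation_gt_60min_non_anaesthetic}
  - predicate_id: in_int_hysterectomy
    category: management
    indian_section: intervention
    expression: {flag: hysterectomy}
  - predicate_id: in_int_dialysis
    category: management
    indian_section: intervention
    expression: {flag: dialysis_acute_renal_failure}
  - predicate_id: in_int_transfusion_ge_5
    category: management
    indian_section: intervention
    expression: {measurement: transfusion_units, cmp: '>=', value: 5}
  - predicate_id: in_int_cpr
    category: management
    indian_section: intervention
    expression: {flag: cpr}
  # cardiorespiratory collapse shortcut
  - predicate_id: in_collapse_cardiac_arrest
    category: clinical
    indian_section: collapse
    expression: {flag: cardiac_arrest}
  - predicate_id: in_collapse_gasping
    category: clinical
    indian_section: collapse
    expression: {flag: gasping}
  - predicate_id: in_collapse_cpr
    category: management
    indian_section: collapse
    expression: {flag: cpr}
  - predicate_id: in_collapse_intubation_ventilation
    category: management
    indian_section: collapse
    expression: {flag: intubation_ventilation_gt_60min_non_anaesthetic}
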