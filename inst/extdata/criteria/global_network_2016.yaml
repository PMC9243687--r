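# Global Network Near-Miss Maternal Mortality System, 2016.
# WHO tool without the laboratory criteria, blood transfusion of any
# volume instead of >= 5 units, plus eclampsia.
set_id: global_network_2016
label: Global Network criteria, 2016
combinator: any_one
predicates:
  - predicate_id: gn_clin_acute_cyanosis
    category: clinical
    expression: {flag: acute_cyanosis}
  - predicate_id: gn_clin_gasping
    category: clinical
    expression: {flag: gasping}
  - predicate_id: gn_clin_respiratory_rate
    category: clinical
    expression: {measurement: respiratory_rate_per_min, outside: [6, 40]}
  - predicate_id: gn_clin_shock
    category: clinical
    expression: {flag: shock}
  - predicate_id: gn_clin_cardiac_arrest
    category: clinical
    expression: {flag: cardiac_arrest}
  - predicate_id: gn_clin_oliguria
    category: clinical
    expression: {flag: oliguria_nonresponsive}
  - predicate_id: gn_clin_clotting_failure
    category: clinical
    expression: {flag: failure_to_form_clots}
  - predicate_id: gn_clin_loss_of_consciousness
    category: clinical
    expression: {flag: loss_of_consciousness_gt_12h}
  - predicate_id: gn_clin_stroke
    category: clinical
    expression: {flag: stroke}
  - predicate_id: gn_clin_fits
    category: clinical
    expression:
      any_of:
        - {flag: uncontrollable_fits}
        - {flag: status_epilepticus}
  - predicate_id: gn_clin_total_paralysis
    category: clinical
    expression: {flag: total_paralysis}
  - predicate_id: gn_clin_jaundice_preeclampsia
    category: clinical
    expression:
      any_of:
        - {flag: jaundice_with_preeclampsia}
        - all_of:
            - {flag: jaundice}
            - {flag: preeclampsia}
  - predicate_id: gn_clin_eclampsia
    category: clinical
    expression: {flag: eclampsia}
  - predicate_id: gn_mgmt_vasoactive_drugs
    category: management
    expression: {flag: vasoactive_drug_use}
  - predicate_id: gn_mgmt_cpr
    category: management
    expression: {flag: cpr}
  - predicate_id: gn_mgmt_intubation_ventilation
    category: management
    expression: {flag: intubation_ventilation_gt_60min_non_anaesthetic}
  - predicate_id: gn_mgmt_dialysis
    category: management
    expression: {flag: dialysis_acute_renal_failure}
  - predicate_id: gn_mgmt_transfusion_any
    category: management
    expression: {measurement: transfusion_units, cmp: '>=', value: 1}
  # retains the WHO management tier: hysterectomy for haemorrhage counts as
  # a surgical procedure to stop bleeding
  - predicate_id: gn_mgmt_surgery_for_bleeding
    category: management
    expression:
      any_of:
        - {flag: surgical_intervention_for_bleeding}
        - {flag: hysterectomy}
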