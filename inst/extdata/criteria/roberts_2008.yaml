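# Roberts 2008 maternal morbidity outcome indicators.
# ICD diagnosis/procedure code groups abstracted to condition and
# management flags (one flag per concept row); an ICD-10 -> token mapping
# is an ingest-time concern, not part of the rule set.
set_id: roberts_2008
label: Roberts morbidity outcome indicators, 2008
combinator: any_one
predicates:
  - predicate_id: roberts_shock
    category: clinical
    expression: {flag: shock}
  - predicate_id: roberts_cardiac_failure
    category: clinical
    expression: {flag: cardiac_failure}
  - predicate_id: roberts_cardiac_arrest_or_infarction
    category: clinical
    expression:
      any_of:
        - {flag: cardiac_arrest}
        - {flag: myocardial_infarction}
  - predicate_id: roberts_obstetric_embolism
    category: clinical
    expression: {flag: obstetric_embolism}
  - predicate_id: roberts_acute_severe_asthma
    category: clinical
    expression: {flag: acute_severe_asthma}
  - predicate_id: roberts_assisted_ventilation
    category: management
    expression:
      any_of:
        - {flag: intubation_ventilation_gt_60min_non_anaesthetic}
        - {flag: tracheostomy}
  - predicate_id: roberts_acute_renal_failure
    category: clinical
    expression: {flag: acute_renal_failure}
  - predicate_id: roberts_dialysis
    category: management
    expression: {flag: dialysis_acute_renal_failure}
  - predicate_id: roberts_transfusion_any
    category: management
    expression: {measurement: transfusion_units, cmp: '>=', value: 1}
  - predicate_id: roberts_dic
    category: clinical
    expression: {flag: dic}
  - predicate_id: roberts_sickle_cell_crisis
    category: clinical
    expression: {flag: sickle_cell_crisis}
  - predicate_id: roberts_cerebral_oedema_or_coma
    category: clinical
    expression: {flag: cerebral_oedema_or_coma}
  - predicate_id: roberts_status_epilepticus
    category: clinical
    expression: {flag: status_epilepticus}
  - predicate_id: roberts_cerebrovascular_accident
    category: clinical
    expression: {flag: cerebrovascular_accident}
  - predicate_id: roberts_uterine_rupture_or_repair
    category: management
    expression:
      any_of:
        - {flag: ruptured_uterus}
        - {flag: uterine_rupture_repair}
  - predicate_id: roberts_hysterectomy
    category: management
    expression: {flag: hysterectomy}
  - predicate_id: roberts_surgery_for_bleeding
    category: management
    expression: {flag: surgical_intervention_for_bleeding}
  - predicate_id: roberts_other_laparotomy
    category: management
    expression: {flag: laparotomy_other}
  - predicate_id: roberts_anaesthesia_complication
    category: clinical
    expression: {flag: anaesthesia_complication}
  - predicate_id: roberts_acute_abdomen
    category: clinical
    expression: {flag: acute_abdomen}
  - predicate_id: roberts_acute_psychosis
    category: clinical
    expression: {flag: acute_psychosis}
  - predicate_id: roberts_acute_appendicitis
    category: clinical
    expression: {flag: acute_appendicitis}
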