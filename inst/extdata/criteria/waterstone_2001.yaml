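# Waterstone 2001 clinical-diagnosis criteria.
set_id: waterstone_2001
label: Waterstone clinical criteria, 2001
combinator: any_one
predicates:
  - predicate_id: waterstone_severe_preeclampsia
    category: clinical
    expression: {flag: severe_preeclampsia}
  - predicate_id: waterstone_eclampsia
    category: clinical
    expression: {flag: eclampsia}
  - predicate_id: waterstone_hellp
    category: clinical
    expression: {flag: hellp}
  - predicate_id: waterstone_severe_sepsis
    category: clinical
    expression: {flag: severe_sepsis}
  - predicate_id: waterstone_severe_bleeding
    category: clinical
    expression: {flag: severe_bleeding}
  - predicate_id: waterstone_ruptured_uterus
    category: clinical
    expression: {flag: ruptured_uterus}
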