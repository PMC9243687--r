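# mnmtool

Maternal near-miss surveillance with multiple criteria sets.

A **maternal near miss (MNM)** is a woman who nearly died but survived a
complication of pregnancy, childbirth, or the 42 days after the end of
pregnancy. Facility audits count near misses alongside maternal deaths
(MD) because their balance reflects quality of care. The standard
process indicators, over a period with *LB* live births, are

- MNM ratio = MNM / LB × 1000
- severe maternal outcome (SMO) ratio = (MNM + MD) / LB × 1000
- mortality index = MD / (MNM + MD) × 100 (lower is better)
- MNM:MD ratio = MNM / MD (higher is better)

Which women count as near misses depends on the criteria set. This
package makes seven widely used sets executable against a single record
vocabulary — the WHO 2011 near-miss tool (25 severity indicators: 12
clinical, 7 laboratory, 6 management), Mantel 1998, Waterstone 2001,
Roberts 2008, the Indian national consensus criteria 2014 (a
three-section combination rule with a cardiorespiratory-collapse
shortcut), the Global Network criteria 2016 (the WHO tool without its
laboratory tier, with transfusion of any volume), and the CDC 2017
indicators — plus the WHO potentially-life-threatening-condition (PLTC)
screen. It computes the process indicators per set, compares the sets on
the identical cohort, runs a transfusion-threshold sensitivity analysis,
and generates seeded synthetic cohorts calibrated to published marginal
frequencies so everything is testable without patient data.

It is aimed at obstetric quality-of-care and severe-maternal-morbidity
epidemiology work: classifying a facility cohort under competing
definitions, quantifying how the definition moves the indicators, and
checking which definitions miss women who die.

## Worked example

A survivor whose only severity indicator is a six-unit blood
transfusion:

```r
library(mnmtool)
r <- patient_record("w1", transfusion_units = 6)
classify(r, "who_2011")
#   record_id   set_id positive                   matched   verdict
# 1        w1 who_2011     TRUE who_mgmt_transfusion_ge_5 near_miss
```

She is a near miss under the WHO tool (transfusion ≥ 5 units), also
positive under Global Network (any-volume transfusion), and negative
under Waterstone (none of its six clinical diagnoses). The `matched`
column carries the provenance: exactly which predicates fired.

Cohort-level reporting takes counts (or classification results) and a
live-birth denominator. With 323 near misses, 57 identified deaths and
0 missed deaths against 37 590 live births:

```r
present_report(indicator_report(323, 57, 0, 37590, "who_2011"))
#     set_id n_near_miss n_deaths_identified n_deaths_missed n_smo live_births
# 1 who_2011         323                  57               0   380       37590
#   mnm_ratio_per_1000 smo_ratio_per_1000 mortality_index_pct mnm_to_md_ratio
# 1                8.6               10.1                  15            5.67
```

i.e. an MNM ratio of 8.6 per 1000 live births, an SMO ratio of 10.1, a
mortality index of 15% and 5.67 near misses per death. Full-precision
values are always retained; `present_report()` only applies the
conventional rounding.

## Analysis workflow

`analysis/` holds the numbered drivers, each a thin script over the
package that prints what it found and writes tables under `results/`:

1. `01_simulate.R` — generate the default synthetic cohort (1833 PLTC
   women, 37 590 live births) and its marginal-recovery diagnostic;
2. `02_classify.R` — per-record verdicts under all seven sets plus the
   PLTC screen;
3. `03_indicators.R` — the cross-criteria comparison table on the
   synthetic cohort, the indicators recomputed from published per-set
   counts, headline rates, and the case-fatality table;
4. `04_transfusion.R` — near miss by units transfused and the
   transfusion cut-off sweep.

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
and so on. Criteria sets and the indicator vocabulary are YAML documents
under `inst/extdata/`; user-supplied YAML in the same grammar defines
custom sets (see `load_criteria()`).

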