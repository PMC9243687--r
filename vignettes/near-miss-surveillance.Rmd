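---
title: "Maternal near-miss surveillance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal near-miss surveillance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnmtool)
```

## The surveillance problem

A maternal near miss is a woman who nearly died but survived a
complication of pregnancy, childbirth, or the 42 days after the end of
pregnancy. Facilities audit near misses alongside maternal deaths because
the two together describe the burden of severe maternal outcomes (SMO =
near misses + deaths), while their balance describes quality of care: when
care is good, most women with life-threatening events survive, so the
mortality index (deaths / SMO × 100) is low and the near-miss-to-death
ratio (MNM:MD) is high.

Which women count as near misses depends on the criteria set in use. The
WHO 2011 near-miss tool defines 25 severity indicators in three tiers —
12 clinical signs, 7 laboratory thresholds, 6 management markers — with
any single indicator sufficing. Alternatives trade sensitivity for
feasibility: Mantel 1998 (organ dysfunction and management), Waterstone
2001 (six clinical diagnoses), Roberts 2008 and CDC 2017 (ICD code
groups, here abstracted to concept flags), the Global Network 2016
criteria (the WHO tool without its laboratory tier, for settings without
reliable laboratory services, with blood transfusion of any volume), and
the Indian national consensus criteria 2014, which use a combination
rule rather than a single-indicator rule. The package makes all of these
executable against one record vocabulary so that the same cohort can be
classified under every set and the resulting indicator sets compared.

## The record model and the missingness rule

Every record carries flag tokens (present/absent) and measurement tokens
(numeric, with a canonical unit, possibly missing). The central semantic
choice is that **a missing measurement never satisfies a threshold
predicate**: a woman without a platelet count is not severely
thrombocytopenic for classification purposes. Classification asserts
severity only from observed data; this mirrors the motivation for
laboratory-free criteria sets in settings where tests are not uniformly
available, and it makes every set's positive count a lower bound with
respect to unmeasured pathology.

Laboratory thresholds that circulate in two unit systems (creatinine
≥ 300 µmol/L ≡ 3.5 mg/dL; bilirubin > 100 µmol/L ≡ 6.0 mg/dL) are stored
once, in mg/dL, and µmol/L columns are converted at ingest (÷ 88.4 and
÷ 17.1) via a units directive in the CSV header. A single canonical
threshold avoids the drift that comes from maintaining both twins.
Transfusion is counted in integer units of whole blood or packed red
cells, pooled, because the criteria sets use the two products
interchangeably; fractional units are rejected at ingest.

Two details of the shipped predicate tables deserve a note. The WHO
transfusion cut-off is implemented as **≥ 5 units** and the WHO
thrombocytopenia threshold as **≤ 50 000/mm³**; published renderings of
the tool vary between strict and non-strict forms of both, and the
package follows the forms used in the tool's own criteria table. The
composite indicator "jaundice in the presence of pre-eclampsia" is
satisfiable by either a provider-asserted composite flag or the
conjunction of plain `jaundice` and `preeclampsia` flags; the compound
route is preferred because it needs no bespoke data collection.

## Combination rules

All sets except the Indian criteria are `any_one`: one true predicate
makes the record positive. The Indian 2014 rule is `indian_sections`:
positive when at least one criterion holds in *each* of the clinical
findings, investigations, and interventions sections, or when any single
criterion signifying cardiorespiratory collapse holds. The full national
indicator roster (more than a hundred variables) is not available in
machine-readable form; the shipped default partitions the WHO indicators
into the three sections by their tier (clinical → findings, laboratory →
investigations, management → interventions) with a four-item collapse
shortcut (cardiac arrest, gasping, CPR, prolonged non-anaesthetic
ventilation). The combination logic, not the roster, is the defining
feature of the Indian approach, and the roster is user-overridable
through the YAML criteria format. Because the shipped roster is narrower
than the national one, the Indian column of any comparison computed here
underestimates more strongly than the published implementation does —
the direction of the effect (marked underestimation, including missed
deaths) is preserved.

One mapping choice in the Global Network set: its procedures row
("surgical procedure to stop bleeding") is satisfied by either the
surgery-for-bleeding flag or hysterectomy. The set is defined as the WHO
tool minus the laboratory tier, and the WHO management tier includes
hysterectomy following infection or haemorrhage; excluding it would let
the Global Network criteria miss deaths whose only non-laboratory
indicator is hysterectomy, contradicting the set's defining property of
catching every death the WHO tool catches.

The engine evaluates each predicate as a vectorised logical column over
the cohort; the test suite checks it record-by-record against an
independent brute-force evaluator that enumerates every sub-expression
naively, and enumerates the Indian combinator's full 16-case truth table
on a section-disjoint predicate set.

## Indicators and rounding

The four process indicators are computed from counts at full precision:
MNM ratio = MNM / live births × 1000; SMO ratio = (MNM + identified
deaths) / live births × 1000; mortality index = identified deaths /
(MNM + identified deaths) × 100; MNM:MD = MNM / identified deaths. The
live-birth denominator is always an explicit parameter — never inferred
from cohort size, because the severe cohort is a small fraction of the
births it is drawn from. Per set, only the deaths that set identifies
enter its SMO count; deaths it misses are reported in a separate column.
A set identifying no deaths has an undefined MNM:MD, reported as `NA`
and serialised as `null`, never as infinity. The maternal mortality
ratio (deaths / live births × 100 000) and PLTC incidence (per 1000) are
computed the same way.

Presentation rounding is round-half-away-from-zero, to 1 decimal for
ratios and the mortality index and 2 decimals for MNM:MD, and is applied
only in `present_report()`; the full-precision values always travel
alongside in reports and JSON. Published comparison tables of this kind
mix rounding with truncation in a few cells and occasionally print
indicator values inconsistent with their own printed counts; this
package always computes from counts, so such cells will differ in the
last digit from some published renderings.

## The synthetic cohort generator

No patient-level data ship with the package. The generator emulates the
marginal structure of a three-year single-facility referral cohort:
1833 women with potentially life-threatening conditions against 37 590
live births, overlapping condition-category prevalences (hypertensive
0.567, medical 0.644, haemorrhage 0.112, infection 0.055, labour-related
0.009), an SMO fraction of 380/1833, a death fraction of 57/1833, and
the 25 WHO indicator frequencies conditional on SMO (e.g. transfusion
≥ 5 units 0.284, severe thrombocytopenia 0.268, clotting failure 0.245,
prolonged ventilation 0.211).

Indicators among SMO records are independent Bernoulli draws — the
published margins carry no joint distribution, and inventing one would
be a stronger assumption than independence. Because an SMO record must
carry at least one indicator, the generator draws indicator vectors
*conditioned on at least one success*, by rejection sampling from base
rates calibrated so that the conditional marginals equal the published
frequencies exactly (the deflation factor solves
`1 − prod(1 − c·p) = c`). Naively forcing a token into empty draws would
inflate every marginal by ~13% relative and fail the package's own
recovery diagnostic, which requires every parameter within four binomial
standard deviations at n = 50 000.

Measurement-type indicators materialise as values drawn uniformly from a
clinically bounded severe range (platelets 5 000–49 999/mm³ for the
thrombocytopenia token, pH 6.8–7.09, and so on); records without the
token leave the measurement missing. A deliberately small consistency
layer injects the only correlations: SMO records acquire the severe form
of their condition category (severe pre-eclampsia / eclampsia / HELLP,
severe bleeding, severe sepsis) so that the condition-defined Waterstone
and Mantel sets see realistic signal, every record gets a screen-tier
flag for its category so the PLTC screen and case-fatality table have
denominators, and a HELLP flag without the severe-thrombocytopenia token
shows a sub-screen platelet count (51 000–99 000/mm³).

Deaths are drawn at the overall death fraction and assigned among SMO
records carrying at least one clinical or management indicator. This is
a selection rule, not a modification of any record, so it leaves the
indicator marginals untouched while guaranteeing — as in the study
population — that the WHO and Global Network sets miss no deaths.
Setting `atypical_death_fraction > 0` kills a fraction of non-SMO
records (which carry no severity indicator) to exercise missed-death
accounting in every set.

Transfusion is the one margin the published material gives only
qualitatively (a figure without printed bar heights, plus the statement
that 407 women received at least one unit and that every woman at five
or more units was a near miss). Transfused units follow a truncated
geometric distribution (parameter 0.45) on 1–10: records with the
≥ 5-unit indicator draw from 5–10, and other records are transfused 1–4
units with probability 299/1725 (consistent with 407 transfused women of
whom 108 received ≥ 5 units). The truncation keeps incidental ≥ 5-unit
draws from leaking outside the SMO stratum, preserving the construction
guarantees above; both the distribution and the transfused fraction are
overridable spec parameters.

What the generator does **not** emulate: joint indicator structure
beyond the consistency layer (so multi-indicator co-occurrence rates are
products of marginals), within-death indicator mixes (deaths are uniform
over eligible SMO records), Indian-roster-specific indicators beyond the
WHO partition, sociodemographics, and any seasonal or referral-pattern
structure. Tests that pass on synthetic cohorts therefore validate the
engine's logic and the indicator arithmetic, not the clinical realism of
any particular joint distribution.

## Numerical and interface choices

* Matched-predicate lists sort lexicographically by predicate id, so
  outputs are byte-stable; reruns of the pipeline with the same seed are
  file-identical.
* The generator restores the caller's RNG state; determinism lives in
  the spec's own seed.
* Degenerate inputs: empty cohorts produce zero-count reports (mortality
  index 0, MNM:MD `NA`), not errors; `live_births = 0` and negative
  transfusion units are hard errors; an unknown token in a criteria file
  is a configuration error naming the predicate, raised at load, before
  any classification.
* Problem sizes: the regular suite exercises the oracle on 400-record
  random cohorts and recovery at n = 20 000; the acceptance checks use
  10 000 random records and n = 50 000, sizes at which four binomial
  standard deviations separate real calibration faults from noise while
  the whole suite still runs in about a minute.

## Known limitations

Roberts 2008 and CDC 2017 are ICD-code systems; the package operates on
their concept rows as flags and leaves ICD-10 code-to-token mapping to
ingest-time configuration, so code-list fidelity is the data provider's
responsibility. "Shock" is a clinician-asserted flag with no
blood-pressure definition, as in the source criteria tables. The Indian
roster caveat above applies to any absolute count computed under
`indian_2014`. No confidence intervals accompany the indicators — they
are surveillance descriptives, and the package deliberately reports them
as such.
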