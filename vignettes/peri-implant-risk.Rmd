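---
title: "Peri-implant disease risk assessment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-implant disease risk assessment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantrisk)
library(dplyr)
```

## The problem

Peri-implant diseases — mucositis (soft-tissue inflammation around a dental
implant without bone loss) and peri-implantitis (inflammation with
progressive loss of supporting bone) — are common enough that clinicians
want a quick, structured way to judge which implants are at risk before
disease is established. `implantrisk` implements an additive risk
rubric for exactly this purpose, together with a three-way diagnostic
classifier and the cohort-level statistics used to relate risk factors to
observed disease.

## The additive risk model

Ten clinical and radiographic parameters are recorded per implant.
Nine of them carry rubric weight; each is graded to an ordinal score and
each score carries a risk percentage:

| Parameter | Levels | Max % |
|---|---|---|
| Periodontal history + compliance | absent/compliant (0) … present/noncompliant (12.5) | 12.5 |
| Plaque status (MPI 0–3) | 0, 2.5, 5.0, 7.5 | 7.5 |
| Gingival status (MGI 0–3) | 0, 2.5, 5.0, 7.5 | 7.5 |
| Random glucose (mg/dl) | <102 → 0 … ≥134 → 12.5 | 12.5 |
| Smoking (cigarettes/day) | nonsmoker 0 … >20/day 12.5 | 12.5 |
| Residual cement | absent 0 / present 12.5 | 12.5 |
| Occlusal overload | absent 0 / present 12.5 | 12.5 |
| Keratinized width (mm) | ≥2 mm 0 / <2 mm 12.5 | 12.5 |
| Alcohol consumption | absent 0 / present 10.0 | 10.0 |

The total risk percentage is the plain sum of the nine contributions, so
it is always a multiple of 2.5 between 0 and 100 (the nine maxima sum to
100). Categories: **low** below 25%, **moderate** from 25 to 50%
inclusive, **high** above 50%. The boundary values follow the only
internally consistent reading of the published thresholds: 25.0 is
moderate, 50.0 is moderate, anything strictly above 50 is high.

Suppuration is the tenth recorded parameter. It carries no rubric
weight — it enters the diagnostic classifier only. The rubric is
data-driven (`inst/extdata/risk_rubric.yaml`, loaded by
`default_rubric()`), so alternative weightings can be supplied to
`assess_risk()` without touching code; `validate_rubric()` enforces the
structural invariants (unique scores, percentages non-decreasing in
score). The fixed percentage vocabulary {0, 2.5, …, 12.5} and the
100-point cap are properties of the shipped default, asserted in its
tests, not constraints on user rubrics.

```{r}
fx <- study_fixture()
profiles <- assess_risk(fx)
count(profiles, category)
```

### Numerical choices in the scorers

Published grading tables leave boundary values unstated; the package
fixes them once, as follows:

* **Glucose bands** are printed as closed integer ranges with unit gaps
  (102–109, 110–117, …). We use half-open real intervals [102, 110),
  [110, 118), [118, 126), [126, 134), ≥134: every printed integer keeps
  its assignment and non-integer readings (e.g. 109.5) are covered.
* **Keratinized width of exactly 2 mm** is classed sufficient
  (`width >= 2`), matching the usual clinical convention of 2 mm
  adequacy.
* **Smoking**: "20 per day" is exactly 20; "<10" covers anything below
  10; ">20" is 21 and up. A current smoker must report a count —
  omitting it is a validation error, not a silent zero.
* The MGI block of the published rubric repeats the plaque-index wording
  verbatim, an apparent typesetting slip; we keep the 0/2.5/5.0/7.5
  mapping and document the MGI levels in bleeding terms (no bleeding,
  isolated spots, confluent line, profuse), which is how the index is
  defined and how the study reports it.

## The diagnostic classifier

Diagnosis uses five findings per implant: MGI, MPI, suppuration, mean
probing depth over six sites, and crestal bone loss (vertical distance
from the line joining the adjacent teeth's cemento-enamel junctions to
the deepest crest point).

The published criteria table lists suppuration and probing depth >5 mm
as requirements for *both* disease states, yet the study it comes from
reports zero suppuration while classifying all 21 implants as diseased —
the criteria cannot have been applied as a literal conjunction. The
package therefore ships two modes:

* **strict** applies each column as a conjunction of all five criteria
  and returns `indeterminate` when none holds. On any suppuration-free
  cohort every implant is indeterminate, which is surfaced as a warning.
* **pragmatic** (default) is the operational reconstruction: *healthy*
  requires MGI = 0, MPI = 0, no suppuration, mean PD ≤ 5 mm and zero
  bone loss; *peri-implantitis* requires an inflammation sign (MGI ≥ 1,
  suppuration, or MPI ≥ 2) together with bone loss strictly above 2 mm;
  everything else is *mucositis*. The 2 mm threshold is the conventional
  allowance for physiological remodeling, so exactly 2.0 mm stays on the
  mucositis side; a mean PD of exactly 5.0 mm stays healthy-compatible.

The pragmatic rule is total (every valid record gets one of three
labels), monotone in bone loss, and agrees with strict mode wherever a
strict conjunction is satisfiable — all property-tested. The
per-criterion columns (`crit_*`) in `classify_implants()` output let
users see which findings drove each call.

## Cohort statistics

`evaluate_cohort()` cross-tabulates each derived factor (sex, history
score, plaque score, gingival score, diabetes, smoking, cement,
overload, width sufficiency, alcohol, and the resulting risk category)
against the diagnosis and computes the Pearson chi-square. Three
decisions, each validated against the published table it reproduces:

* **No continuity correction.** Back-computing every published 2×2
  statistic shows only the uncorrected statistic reproduces them
  (e.g. the sex table [[0, 7], [4, 10]] gives 2.471).
* **All-zero categories are dropped before the degrees of freedom are
  computed.** The history factor's printed p-value (0.128) corresponds
  to df = 2, i.e. its empty "Score 2" row was excluded; dropped levels
  are recorded in the result.
* **No minimum expected count is enforced.** Small clinical series
  routinely violate the E ≥ 5 rule of thumb (so does the study cohort);
  the package computes the test anyway and logs a warning naming the
  affected factor.

Degenerate factors (a single non-zero level, e.g. suppuration in the
study cohort) are reported with counts but no statistic. The
"test of proportion" companion is implemented as the two-sided pooled
two-sample z-test without continuity correction
(`two_proportion_test()`) — the standard default in clinical reporting;
the source study names the method without printing any z statistics, so
no published value constrains it. Tail probabilities come from the
upper chi-square tail; displayed output is rounded to 3 decimals
(statistics, p-values) and 1 decimal (percentages), with full precision
kept internally.

```{r}
ev <- evaluate_cohort(fx)
tidy(ev) |> select(factor, statistic, df, p_value)
```

## The synthetic cohorts

### The deterministic study fixture

`study_fixture()` reconstructs the 21-implant, 13-patient cohort from
its published factor-by-diagnosis margins (7 female implants all
mucositis; history scores 9/5/0/7; plaque 4/9/6/2; gingival 11/4/6/0;
4 smoking-present implants; 2 overloaded; 5 insufficient-width;
6 alcohol; 15 low / 6 moderate risk; zero suppuration, diabetes and
cement). Only margins are published; the joint assignment of levels to
implants is not identifiable from them. Rather than an arbitrary blocked
assignment — which stacks the heaviest levels onto the same implants and
produces risk totals above 50%, contradicting the published risk-category
margin — the fixture uses a fixed, hand-designed assignment chosen so
that *all* margins hold simultaneously, including the risk-category one,
and so that patient-level attributes (sex, smoking, history, alcohol,
glucose) are constant within each patient. Every published chi-square
statistic depends only on the margins, so any assignment satisfying them
yields the same statistics; the particular one shipped is frozen and
bit-stable (no randomness).

Two published inconsistencies are followed, not resolved: the narrative
"sufficient width in 17 implants (76.2%)" versus the table's 16/5 split
(76.2% = 16/21 — the fixture follows the table), and the narrative's
two smoker *patients* versus four smoking-positive *implants* (patients
carry up to two implants each; the fixture gives the former smoker two
mucositis implants and the current smoker two peri-implantitis
implants). Patient load is fixed at 8 patients with two implants and 5
with one.

Continuous measurements are representative values consistent with the
categorical levels: glucose 92 mg/dl, widths 3.0/1.0 mm, bone loss
1.0 mm (mucositis) vs 3.0 mm (peri-implantitis), six-site probing
depths averaging 4.0 vs 6.0 mm.

### The stochastic generator

`generate_cohort()` samples cohorts from a `cohort_spec()`: patients
(sex at patient level), implants per patient, a diagnosis per implant,
then factor levels from per-diagnosis conditional probabilities. The
defaults are the study conditions — 13 patients with 1–2 implants,
5/13 female, prevalence (0, 17/21, 4/21), and conditional factor
probabilities equal to the study margins. Records are built so the
pragmatic classifier recovers the sampled diagnosis: healthy implants
carry no inflammation sign and zero loss; peri-implantitis implants get
an MGI of at least 1 if no other sign was drawn, plus bone loss of
3 mm. All randomness flows through `spec$seed` (restored afterwards via
`withr`), so identical specs give identical cohorts.

What the generator does *not* emulate: within-patient correlation of
implant-level factors other than the patient-level ones listed above;
continuous within-band variation (glucose, depths and widths are
representative constants); longitudinal progression; and measurement
error. Passing tests on generated data therefore demonstrate the
arithmetic and logic of the pipeline, not calibration against real
clinical variability.

## Problem sizes and runtime

The test suite works at the study's own scale (21 implants) for all
published-value checks; property tests use 40–60 random contingency
tables up to 5×5, a findings grid of 480 combinations for classifier
totality, and a 10,000-implant generated cohort for the binomial
convergence check of the generator — the whole suite runs in well under
a minute on a single CPU.

## Known limitations

* The pragmatic diagnostic rule is a documented reconstruction of how
  the published criteria must have been operationalized; it is flagged
  as such and the strict reading remains available.
* The published rubric's duplicated MGI wording is resolved in favor of
  the printed score/percentage numbers, with bleeding-based level
  descriptions; the rubric's nine maxima total 100, which is the cap
  the package enforces.
* Chi-square p-values at these sample sizes are approximations; the
  package reproduces the published analysis rather than recommending it
  (an exact test would be the better choice at n = 21, and is
  deliberately out of scope).
* Patient-level clustering (multiple implants per patient) is ignored by
  the tests, as in the source analysis: implants are treated as
  independent units.
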