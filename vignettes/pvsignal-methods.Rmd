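---
title: "Methods: disproportionality signal detection in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect voluntary
reports of suspected drug reactions. They have no exposure denominators and
severe reporting biases, so the only defensible primary analysis is
*disproportionality*: is the (drug, event) pair reported more often than one
would expect if drug and event were independent across the database?
`pvsignal` implements this analysis for a cohort of antidepressant reports
in patients treated for depression / major depressive disorder (MDD), with
four cardiac-arrhythmia endpoint groups — QT prolongation / Torsades de
Pointes (TdP), atrial fibrillation, heart block, and ventricular arrhythmia
— and pairwise between-drug contrasts on event composition and outcome
severity.

## From raw quarters to an analysis cohort

**Parsing.** Quarterly extracts arrive as five `$`-delimited ASCII tables
(DEMO, DRUG, REAC, OUTC, INDI). Files are read as Latin-1 (the extracts are
not valid UTF-8), column names are mapped through a configurable schema
profile so dialect drift across quarters is a configuration change, and rows
that cannot be used (missing identifiers, unlinkable mentions, invalid role
or outcome codes, blank reaction terms) are routed to a rejects log with a
file/line/reason record rather than silently dropped. Ages are normalized to
years from the unit codes `YR`, `DEC`, `MON`, `WK`, `DY`, `HR`; an unknown
unit, or a normalized age outside (0, 120), is treated as missing rather
than guessed. Weights are normalized to kg (`KG`, `LBS`, `GMS`). Missing
sex, country or weight become explicit `unknown` categories, never exclusion
criteria, because descriptive tables in this field report unknown strata.

**Deduplication.** A case accumulates report versions as follow-up arrives.
The rule here is the conventional one for FAERS: per case identifier, keep
the version with the latest FDA receipt date, breaking ties by the largest
report-version identifier; undated versions lose to dated ones. The number
of dropped versions is reported so cohort sizes are auditable. The rule is
idempotent, and applying it across any partition of the quarters gives the
same result as applying it once to the union.

**Cohort and mapping.** The analysis cohort is the set of deduplicated cases
carrying at least one qualifying indication term (default: `Depression`,
`Major depression`; exact match after case-folding — deliberately narrow, so
the cohort definition is transparent and configurable). Exposure to one of
the study drugs is a *suspect-role* mention (primary or secondary suspect);
concomitant and interacting mentions do not count. This is the conservative
pharmacovigilance convention; counting all mentions would dilute suspect
drugs with background co-medication. Verbatim drug names are matched by
exact lookup after normalization (case-fold, trim, dose-token removal, salt
and formulation suffix stripping); there is no fuzzy matching, so a
misspelled verbatim name is simply unmatched rather than probabilistically
assigned. Reaction preferred terms (PTs) are mapped onto the four endpoint
groups by flat set membership. The shipped endpoint lists are **editable
placeholders in the style of SMQ-narrow groupings**: licensed MedDRA SMQ
content is not redistributed, and users with a MedDRA license should
substitute the licensed narrow-scope PT lists via the YAML dictionary. The
four groups must be pairwise disjoint (enforced at load time) because the
endpoints are tabulated separately.

## The contingency tables

For drug *D* and endpoint *E* over a cohort of *N* cases:

|              | event *E* | other events |
|--------------|-----------|--------------|
| drug *D*     | a         | c            |
| other drugs  | b         | d            |

One case contributes once per (drug-exposure, endpoint-status) combination:
a case on two study drugs appears in both drugs' rows, and a case with PTs
in two endpoint groups counts toward both endpoints, so every row sums to
the same grand total *N* and, within an endpoint, the event margin `a + b`
is identical across drugs.

## The statistics

* **PRR** `= [a/(a+c)] / [b/(b+d)]`, CI
  `exp(ln PRR ± 1.96 √(1/a − 1/(a+c) + 1/b − 1/(b+d)))`. Not estimable when
  `a = 0` or `b = 0`.
* **ROR** `= ad/(bc)`, Woolf CI `exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`.
  Not estimable when any cell is zero; the headline analysis applies no
  continuity correction (the pairwise module does, see below).
* **Yates chi-square** `= N·(max(0, |ad−bc| − N/2))² / [(a+b)(c+d)(a+c)(b+d)]`.
  The continuity correction, with clamping at zero, is what reproduces the
  published statistics this package regression-tests against (the
  uncorrected statistic does not); it also agrees with
  `stats::chisq.test(correct = TRUE)`, which the test suite uses as an
  independent cross-check.
* **Information component** (BCPNN family), in the single-shrinkage
  approximation: with `E = (a+b)(a+c)/N`, `IC = log2((a+0.5)/(E+0.5))`, and
  asymmetric credibility bounds
  `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`,
  `IC975 = IC + 2.4(a+0.5)^{−1/2} − 0.5(a+0.5)^{−3/2}`. The +0.5 shrinkage
  keeps every configuration estimable and pulls small-count pairs toward
  independence. The exact posterior-moment BCPNN is out of scope; the
  approximation above is the form whose values match the published table
  this package checks itself against, cell by cell.
* **Signal flags**: PRR signal iff `a ≥ 3 ∧ PRR ≥ 2 ∧ χ² ≥ 4` (the Evans
  criterion); ROR signal iff `a ≥ 3` and the lower CI bound exceeds 1; IC
  signal iff `IC025 > 0`. These are the standard criteria, and the full
  32-row regression confirms they reproduce the published signal
  highlighting exactly. No multiple-testing adjustment is applied anywhere —
  this mirrors standard practice for these screening statistics and is a
  known limitation: across 32 pairs and three criteria, some flags are
  expected under the null.

## Pairwise comparisons

**Constituent ratio.** Within an endpoint, two drugs are contrasted on the
composition of their own report sets: `OR = (a_i·c_j)/(a_j·c_i)`, i.e. the
odds of an endpoint report given drug *i* versus drug *j*, with a Woolf CI.
This is the operationalization that reproduces the published pairwise
contrasts from the published contingency cells (all twenty printed OR/CI
triples, to ±0.01). When any cell is zero the Haldane–Anscombe +0.5 is added
to all four cells and the result is marked `corrected`. The full matrix is
antisymmetric by construction: unit diagonal, `OR(i,j)·OR(j,i) = 1`, and
reciprocal interval bounds, exact to floating tolerance.

**Severity.** Among a drug's endpoint-positive reports with at least one
outcome record, *severe* means death or a life-threatening event was
reported; all other serious outcome codes (hospitalization, disability,
congenital anomaly, required intervention, other serious) count as
non-severe for this contrast. Reports with no outcome record are excluded
from the denominators: treating them as non-severe would be an unverifiable
assumption, and the descriptive tables in this field show the unknown
stratum is large. The severe set is configurable in the generator and
documented here because published analyses rarely enumerate it. The source
study's per-drug severe/non-severe counts are not published, so the severity
contrast is validated only against planted ground truth on synthetic data,
never against printed values.

## The synthetic generator

`simulation_config()` defaults encode the study conditions: the eight
antidepressants at their observed report-margin shares of the 746,507-report
cohort, the four endpoints at their observed background reporting rates
(2671 / 689 / 655 / 616 events over 746,507), a 5% duplicate-version rate, a
90% depression-indication share, and the 2015Q1–2023Q3 quarter window.
Reports are independent draws: one suspect drug (catalog share or an
unrelated-drug pool), endpoint reactions at `background rate × planted
reporting-rate ratio` (a configuration whose product exceeds 1 is rejected
as ill-posed), one to a few neutral filler PTs from a fixed 50-term
vocabulary, outcome codes from a per-(drug, endpoint) severity split
(default 0.35 severe / 0.60 other-serious / 0.05 none for endpoint reports),
and an indication term. Duplicate versions get a later receipt date and a
higher version identifier, so the deduplication rule is exercised with known
truth. Same seed, same bytes.

What the generator does **not** emulate: drug–drug interaction or masking
effects, correlated reporting within reporters or countries, realistic
marginal distributions of weight, country or co-medication counts, reporting
trends over time, or misspelled verbatim names. Passing tests therefore
demonstrate that the estimators and thresholds behave correctly under the
stated sampling model — not that the pipeline is robust to every artifact of
real spontaneous-report data.

With one planted pair per endpoint, the pair's comparator ("all other
drugs") keeps the pure background rate, so ROR converges to the planted
ratio and IC to its base-2 log as *n* grows; the test suite checks interval
coverage at *n* = 200,000 (planted ratios 4, 2, 1, 0.25) and checks that the
`IC025 > 0` false-flag fraction stays at or below 5% over 200 null pairs at
the same size. Planting several elevated drugs on the *same* endpoint
contaminates the shared event margin and biases each pair's comparator
upward — a real phenomenon (competition/masking bias), but one that would
make a naive convergence test wrong, which is why the recovery experiment
uses distinct endpoints.

## Numerical and reporting conventions

* All statistics are computed in double precision from the raw cells;
  rounding (2 decimals for ratios and IC bounds, 3 for chi-square) happens
  only at the reporting edge.
* Quantiles for descriptive medians/IQRs use `stats::quantile(type = 6)`,
  the `(n+1)p` linear-interpolation convention of the major biostatistics
  packages — e.g. ages {37, 53, 69} give median 53 with quartiles (37, 69),
  where R's default type 7 would give (45, 61). The convention is stated
  because published quartiles are generally not recomputable from summary
  data; the choice only needs to be explicit and stable.
* For a specific outcome in descriptive breakdowns, `yes` means the code was
  reported, `no` means other outcome codes were reported but not this one,
  and `unknown` means the report carries no outcome record — the only
  decomposition available from the outcome table alone.
* Deduplication tie-breaks compare version identifiers numerically when they
  parse as numbers, falling back to string order.

## Known inconsistencies in the shipped reference counts

The shipped 32-row counts fixture transcribes a published table whose cells
allow every statistic to be recomputed. Five printed statistic cells
disagree with recomputation from their own row's counts and are excluded
from the regression tolerance (the counts themselves are kept as printed):
the duloxetine/QT PRR (printed 0.17; the cells give 0.19, matching the
printed ROR), the venlafaxine/AF PRR upper bound (printed 1.81; the cells
give 1.18, matching the printed ROR bound — a digit transposition), the
venlafaxine/QT chi-square (printed 1.418; the cells give 3.584), the
sertraline/VA chi-square (printed 13.787; the cells give 0.094 — a value of
13.787 is impossible for a PRR of 0.95 at that count), and the fluoxetine/VA
IC (printed −0.01; the cells give +0.01, a sign slip at the rounding
boundary). Additionally the duloxetine/QT row is printed with `b = 2701`,
inconsistent with the QT event margin of 2671 carried by the other seven
rows (its own row still sums to 746,507, and its printed chi-square and IC
are reproduced from its printed cells). The tests assert the margin identity
on the 31 consistent rows and pin the anomalous row at its printed value
rather than silently correcting it.

## Problem sizes

The test suite runs its large property checks at 200,000 simulated reports
(estimator recovery and null calibration) and its behavioural checks at
400–40,000 reports; the full suite completes in well under five minutes on
one CPU. These sizes were chosen so that interval-coverage checks are
informative (expected `a` counts from ~3 to ~200) while the suite stays fast
enough to run on every change.

## Limitations

Disproportionality is signal *detection*, not risk estimation: no
denominators, no confounding control, no causal interpretation. The
indication filter is exact-match and the drug matching is exact-after-
normalization, so real-data recall depends on dictionary completeness. The
shipped endpoint lists are placeholders, not licensed SMQ content. The exact
data-cleaning rules that produced the original study's 746,507-report cohort
are not published, so no claim is made of reconstructing that cohort from
raw quarters; the statistical core is instead verified cell-by-cell on the
published counts.
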