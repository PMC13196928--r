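---
title: "Disproportionality signal detection with pvsignal: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the model

Spontaneous reporting systems such as FAERS collect voluntary safety reports.
Each *case* (keyed by CASEID) lists drug mentions with role codes (PS primary
suspect, SS secondary suspect, C concomitant, I interacting) and adverse-event
terms; a case can be re-reported over time as new *versions*, each with its own
PRIMARYID. There is no denominator of drug use, so absolute risks cannot be
estimated. Disproportionality analysis works around this by comparing, within
the database itself, how often an event is reported with a drug versus with all
other drugs. For a drug–event pair over `N` deduplicated cases the 2×2 table has
cells `a` (drug and event), `b` (drug, no event), `c` (event, no drug), `d`
(neither), and the package computes

* the reporting odds ratio `ROR = (a·d)/(b·c)` with the Woolf (log-normal)
  interval `exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d))`,
* the proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with
  `exp(ln PRR ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`,
* the Yates-continuity-corrected χ² of the table.

The two measures are concordant — `(ROR−1)` and `(PRR−1)` always share a sign,
and `ROR/PRR = (1 + a/b)/(1 + c/d)`, so `PRR ≤ ROR` whenever `ROR ≥ 1` — which
the test suite checks exhaustively on small tables. A *signal* is a pair meeting
a pre-set rule; it indicates disproportionate reporting, never causation.

Assumptions worth keeping in mind: the counting unit is the case (set
semantics — repeated mentions of a drug or term within one case count once);
the comparator is every case not mentioning the drug; and reporting behaviour,
not incidence, drives all counts.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `roles` | `c("PS", "SS")` | drug mentions counted as exposure. Suspect-only is the default because disproportionality over concomitant mentions dilutes signals; pass all four codes to widen. |
| `z` | 1.96 | CI multiplier (two-sided 95%). |
| `signal_criteria()` | ROR rule: `a ≥ 3` and CI lower bound `> 1` | the alternative PRR rule (`a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`) is selected with `method = "prr"`. Criteria are configuration, not code. |
| `top_n` | 30 | per-event list length for ranking and intersection. |
| `correction` | `TRUE` | Haldane–Anscombe +0.5 on all four cells, applied **only** when a cell is zero, flagged per pair; with `FALSE`, zero cells raise an error instead of silently producing infinities. |

Ranking is strictly by report frequency `a` (descending), with deterministic
tie-breaks (higher ROR, then drug name). The published tables this package uses
as fixtures are captioned "arranged by frequency" but are not frequency-sorted
throughout, so their printed *order* is treated as unreliable; classification
tests assert set membership and counts, never rank positions.

## Deduplication

The FAERS convention is case-level: for each CASEID keep the highest
CASEVERSION, break ties by latest FDA_DT, then by greatest PRIMARYID. The chain
makes the retained set a deterministic function of the data, so dedup is
idempotent and invariant to input row order (property-tested). Records without
a CASEID cannot be attributed to a case and are retained individually, with a
logged count. Deduplicating "by PRIMARYID" alone would leave one case
represented once per version, inflating every margin.

## Name and term standardization

MedDRA is licensed, so standardization is a contract, not a bundled dictionary:
two-column TSV tables map verbatim drug names and event terms to canonical
forms. Keys are normalized (uppercase, trim, collapse whitespace); unmapped
inputs pass through key-normalized rather than being dropped, so synthetic-data
analyses need no dictionary at all, and mappings are validated to be idempotent
(a canonical name can never be remapped). The packaged `default_synonyms()`
covers only the three brand/generic pairs the pulmonary-hypertension panel
needs (Opsumit→Macitentan, Adempas→Riociguat, Adcirca→Tadalafil); the
treprostinil products Tyvaso, Remodulin and Orenitram are distinct rows in the
published tables and are deliberately not pooled by active ingredient (pooling
is possible by supplying a custom table, but off by default).

## The synthetic-report generator

`synthetic_config()` + `simulate_reports()` emulate the quarterly file
structure with known ground truth: independent Bernoulli drug exposures with
configured marginals; event occurrence on the odds scale — background odds
`p/(1−p)` multiplied by the planted odds ratio ρ of each exposed planted drug,
multiplicatively when a case carries several. With a single planted drug per
event, the case-level exposed/unexposed odds ratio is exactly ρ, so the
pipeline's ROR estimates ρ directly; with several planted drugs on one event
the multiplicative combination makes the single-drug marginal ROR an
approximation of ρ (documented, and avoided in the recovery tests). Dates are
uniform over 2018-01-01..2022-12-31 (the window of the fixture tables) and
decide the quarterly file; `PRIMARYID = CASEID·100 + CASEVERSION` keeps
deduplication transparent; `duplicate_rate` re-emits a case as a later, higher
version. The default `role_mix = c(PS = 0.7, SS = 0.3)` generates suspect-drug
mentions — the roles the analysis counts by default — so the planted odds ratio
is the estimand of the default pipeline; adding concomitant mentions to the mix
models exposure misclassification instead, which is available but not the
default study condition.

What the generator does **not** emulate: correlated co-prescription,
demographic covariates, reporter/country fields, reporting waves, or
event-term hierarchies. Passing recovery tests therefore show the estimators
and plumbing are correct under the stated sampling model, not that real FAERS
signals are unbiased — reporting bias is a property of the data source, not
something any estimator removes.

## Numerical and degenerate-input choices

* Zero cells: Haldane–Anscombe (+0.5 on all four cells) only when a zero is
  present, flagged per pair. A drug or event absent from the data yields a
  degenerate, corrected, never-flagged row rather than an error or a silent
  drop, so panel profiles always have full dimensions.
* χ² uses the textbook Yates form `N(|ad−bc| − N/2)²/∏margins` truncated at
  zero, which matches `stats::chisq.test(correct = TRUE)` to machine precision
  (the test suite asserts this against that independent implementation).
* Printed reports round half-up to two decimals, mirroring the fixture tables;
  full precision is kept internally.
* Ties in ranking and dedup break deterministically (documented above), so
  reruns are byte-identical.

## Problem sizes used by the test suite

The statistical tests run at sizes chosen to make their assertions sharp but
cheap: exhaustive 2×2 grids with cells 1–6 for the formula oracle; 10,000
replicate tables for CI coverage (95% ± 2 percentage points); parameter
recovery at 50,000 cases × 20 seeds for the planted ρ = 10 pair (drug marginal
0.05, event background 0.01), asserting CI coverage in at least 18 of 20
seeds; and a 20-drug × 10-event null panel at 10,000 cases for the
false-positive rate (< 5% flagged under the one-sided CI criterion, nominal
≈ 2.5%).

## Known limitations and documented source conflicts

* The packaged published tables are fixtures *about* a full-scale FAERS
  analysis; they cannot be recomputed at desk scale, and the package makes no
  claim to reproduce their per-pair values — only the classification logic
  applied to them.
* One fixture row (chest pain, Pomalyst) is malformed at the source (printed
  PRR exceeds the printed ROR, impossible for a positive-association table);
  the fixture substitutes the narrative's CI for that row and tests exclude it
  from direction checks.
* The source narrative and its own CI table disagree about riociguat
  (Adempas): all four printed CI lower bounds exceed 1 (10 all-positive panel
  drugs under the CI criterion) while the narrative relates the drug to only
  three symptoms (9, the printed count). Both readings are asserted in the
  acceptance tests; the headline count follows the narrative's drug-level
  statement, and the conflict is surfaced rather than resolved.
* Bayesian disproportionality (BCPNN/IC, EBGM), time-to-onset analysis and
  duplicate-signal shrinkage are out of scope, as are XML-dialect FAERS files
  and the openFDA API.
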