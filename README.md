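# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports, in
the dialect of the FDA Adverse Event Reporting System (FAERS) quarterly ASCII
extracts.

Spontaneous reporting databases collect safety reports in which one case lists
several drugs (with suspect/concomitant role codes) and several adverse-event
terms. Pharmacovigilance signal detection asks, for each drug–event pair,
whether the event is reported disproportionately often with that drug compared
with every other drug in the database. `pvsignal` implements the complete
pipeline for this analysis — quarterly file ingestion, case deduplication,
name/term standardization, 2×2 contingency statistics, per-event top-N ranking,
multi-event intersection classification, and drug-panel profiling — for
epidemiologists and clinical researchers who work with FAERS-style extracts, and
ships a synthetic-report generator with planted effect sizes so every stage can
be validated without downloading FAERS.

## The statistics

For a drug D and event E over N deduplicated cases, the 2×2 table is

|            | event E | not E |
|------------|---------|-------|
| drug D     | a       | b     |
| other drugs| c       | d     |

* **ROR** (reporting odds ratio) = (a·d)/(b·c), with the Woolf log-normal 95% CI
  `exp(ln ROR ± 1.96 · √(1/a + 1/b + 1/c + 1/d))`;
* **PRR** (proportional reporting ratio) = [a/(a+b)] / [c/(c+d)], with
  `exp(ln PRR ± 1.96 · √(1/a − 1/(a+b) + 1/c − 1/(c+d)))`;
* Yates-corrected χ² of the table.

Tables with a zero cell get the Haldane–Anscombe correction (+0.5 to all four
cells, flagged per pair). The default signal rule is `a ≥ 3` and ROR CI lower
bound `> 1`; a PRR rule (`a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`) is available through
`signal_criteria()`. A drug in the top-N list of every analyzed event is a
*high*-signal drug; in exactly all-but-one lists, a *medium*-signal drug.

## Worked example

The package ships the published top-30 medication lists for four
post-lung-surgery symptoms (dyspnoea, cough, palpitations, chest pain; FAERS
Jan 2018 – Dec 2022) as classification fixtures:

```r
library(pvsignal)

venn <- fixture_venn_classification()
venn
#> Multi-event signal classification (4 events)
#>   events: CHEST PAIN, COUGH, DYSPNOEA, PALPITATIONS
#>   high-signal drugs (all 4 lists): Ambrisentan, Entresto, Opsumit, Tyvaso
#>   medium-signal drugs (3 lists): Copaxone, Gilenya, Ibuprofen, Ofev, Orenitram,
#>     Remodulin, Uptravi, Veletri, Xolair, Zejula
glance(venn)
#> # A tibble: 1 × 4
#>   n_events n_drugs n_high n_medium
#> 1        4      67      4       10
```

Four drugs appear in all four lists and ten in exactly three. After mapping
brand to generic names (`Opsumit → MACITENTAN`), three of the four high-signal
drugs belong to the 12-drug pulmonary-hypertension (PH) panel:

```r
intersect(normalize_drug(venn$high_set, default_synonyms()),
          fixture_panel_drugs(canonical = TRUE))
#> [1] "AMBRISENTAN" "MACITENTAN"  "TYVASO"
```

Profiling the PH panel against the published per-cell ROR intervals flags each
drug–event cell by the CI criterion (e.g. Sildenafil is positive only for
dyspnoea and palpitations):

```r
prof <- profile_panel(fixture_panel_ror(canonical = TRUE),
                      panel = fixture_panel_drugs(canonical = TRUE))
prof
#> Drug panel profile: 12 drugs x 4 events
#>   positive for every event: TADALAFIL, RIOCIGUAT, AMBRISENTAN, BOSENTAN,
#>     EPOPROSTENOL, MACITENTAN, ORENITRAM, REMODULIN, TYVASO, UPTRAVI
autoplot(prof)   # ROR heatmap
```

An end-to-end run on synthetic data with a planted odds ratio of 10 for the
TARGETIN–dyspnoea pair (drug marginal 0.05, event background 0.01, 20,000
cases, 20% duplicate reports):

```r
cfg <- synthetic_config(
  n_cases = 20000,
  drugs = c(TARGETIN = 0.05, OTHERMAB = 0.10),
  events = c(DYSPNOEA = 0.01, COUGH = 0.02),
  effects = data.frame(drug = "TARGETIN", event = "DYSPNOEA", rho = 10),
  duplicate_rate = 0.2, seed = 7
)
sim <- simulate_reports(cfg)
cases <- assemble_cases(deduplicate_cases(sim$demo), sim$drug, sim$reac)
compute_signals(cases, events = c("DYSPNOEA", "COUGH"))
#> # A tibble: 4 × 15
#>   drug     event        a     b     c     d   ror ror_low ror_high ... signal
#> 1 OTHERMAB COUGH       40  2021   349 17590 0.998   0.717     1.39     FALSE
#> 2 TARGETIN COUGH       17  1006   372 18605 0.845   0.518     1.38     FALSE
#> 3 TARGETIN DYSPNOEA    93   930   215 18762 8.73    6.78     11.2      TRUE
#> 4 OTHERMAB DYSPNOEA    30  2031   278 17661 0.938   0.642     1.37     FALSE
```

Only the planted pair is flagged, and its CI covers the planted odds ratio.
`run_faers_pipeline(pipeline_config(...))` runs the same stages from quarterly
files on disk and writes the report tables (per-event top-N, Venn membership,
panel matrices).

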