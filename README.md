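# rorscreen

Case/non-case disproportionality screening for spontaneous
adverse-event report databases, built around the renal safety screening
of the BCR-ABL tyrosine kinase inhibitors (imatinib, dasatinib,
nilotinib, bosutinib, ponatinib) and fully testable without access to a
restricted pharmacovigilance database.

It is aimed at pharmacovigilance analysts and methods researchers who
need a reproducible pipeline over individual case safety reports
(ICSRs): a MedDRA-like SOC/HLGT/HLT/PT term hierarchy with the
seven-HLT renal case definition, a three-table ICSR data model with
delimited-text I/O, deterministic duplicate collapsing, rule-based case
selection with an exclusion audit trail, report-level 2×2 screening, and
descriptive cohort/time-to-onset summaries — plus a synthetic ICSR
generator with injected drug–event associations of known strength, so
detection behaviour can be validated against an analytic ground truth.

## The statistic

For an index drug and an event PT set, every report of the deduplicated
database is cross-classified once (a: drug and event, b: event with
other drugs, c: drug without event, d: neither):

    ROR = (a/c)/(b/d) = ad/bc
    CI95 = exp( ln ROR ± 1.96 * sqrt(1/a + 1/b + 1/c + 1/d) )

A signal of disproportionate reporting (SDR) is flagged when — all
strictly — a > 5, ROR > 1 and the lower 95% bound > 1. Tables with a
zero cell are reported as non-computable rather than corrected (a
Haldane–Anscombe +0.5 correction is available opt-in).

## Worked example

```r
library(rorscreen)

dict <- demo_dictionary()                       # bundled synthetic MedDRA stand-in
cfg <- default_synthetic_config(n_reports = 20000, seed = 42,
  signals = signal_spec("NILOTINIB", "PT_NEPHROTIC_SYNDROME", 5))
store <- generate_icsr_store(cfg)               # 20,400 reports (2% duplicates)

sel <- select_cases(store, selection_config(), dict)
sel$audit
#> <selection_audit>
#>   duplicates removed: 400
#>   reports screened:   20000
#>   rejected (window): 395
#>   rejected (reporter): 1994
#>   rejected (drug_role): 15842
#>   rejected (event): 1600
#>   rejected (age): 7
#>   rejected (sex): 6
#>   cases retained:     156

dd <- deduplicate_reports(store)$store
res <- screen_disproportionality(dd, tki_drugs(), studied_pts())
subset(as.data.frame(res), sdr,
       select = c(drug, event, a, b, ror, ci_low, ci_high))
#>         drug              event  a   b  ror ci_low ci_high
#> 18 DASATINIB      Renal failure 11 258 2.24   1.21    4.13
#> 37 NILOTINIB Nephrotic syndrome 23 261 4.38   2.83    6.78
```

The injected pair (nilotinib × nephrotic syndrome, true ROR 5) is
flagged with an estimate of 4.38 whose interval covers the truth; the
second flag is a chance association at this database size — a reminder
that screening without multiplicity adjustment produces false positives,
which is why SDRs are hypotheses, not conclusions. The audit reconciles
exactly: 20000 − (395 + 1994 + 15842 + 1600 + 7 + 6) = 156 cases.

`run_pipeline("inst/extdata/demo_config.json")` (or the
`inst/cli/rorscreen` script with subcommands `simulate`, `select`,
`screen`, `summarize`, `all`) runs everything end to end and writes the
audit, screening results, forest-plot data, characteristics and
time-to-onset tables plus a reproducibility manifest.

## Layout

- `R/` — hierarchy (`meddra.R`), ICSR store (`icsr-store.R`), generator
  (`synthetic.R`), selection (`case-selection.R`), screening
  (`disproportionality.R`), summaries (`summaries.R`), orchestration
  (`pipeline.R`)
- `inst/extdata/` — dictionary fixture, dialect documentation, demo
  pipeline configuration
- `vignettes/methods.Rmd` — models, assumptions, parameter defaults,
  numerical choices and limitations
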