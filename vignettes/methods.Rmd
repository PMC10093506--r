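---
title: "Case/non-case disproportionality screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Spontaneous-report pharmacovigilance databases collect individual case
safety reports (ICSRs): one report describes a patient, the drugs they
took (with roles: suspected, interacting, concomitant) and the adverse
reactions observed, coded as MedDRA preferred terms (PTs). Because there
is no denominator of exposed patients, safety signals are screened by
*disproportionality*: does a drug-event pair appear more often than the
rest of the database would suggest? `rorscreen` implements the
case/non-case design used for screening renal adverse reactions of the
BCR-ABL tyrosine kinase inhibitors (imatinib, dasatinib, nilotinib,
bosutinib, ponatinib), as a reusable pipeline over a documented
three-table ICSR dialect, together with a synthetic database generator
whose true association strengths are known, so that every stage can be
validated end to end without access to a restricted database such as
VigiBase.

## The statistic

For one index drug and one event (a PT set), every report in the
deduplicated database is cross-classified once, at report level:

|              | index drug | all other drugs |
|--------------|-----------|-----------------|
| event        | a         | b               |
| no event     | c         | d               |

The reporting odds ratio and its log-scale Wald (Woolf) interval are

$$ROR = \frac{a/c}{b/d} = \frac{ad}{bc}, \qquad
CI_{95} = \exp\!\left(\ln ROR \pm z\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),
\quad z = 1.96.$$

A *signal of disproportionate reporting* (SDR) is flagged when, all
strictly, `a > 5`, `ROR > 1` and the lower confidence bound exceeds 1.
Both thresholds are configurable (`screen_config()`), and all
inequalities are strict: a lower bound of exactly 1, or a = 5, is not a
signal.

Numerical choices:

* **Zero cells.** If any cell is below 1 the estimate is undefined
  (`NA`, `computable = FALSE`), not an exception. An opt-in
  Haldane–Anscombe correction (`haldane = TRUE`, +0.5 on every cell of
  affected tables) exists for comparability with other tools, but is off
  by default because the reference methodology applies none.
* **Counting unit.** All four cells count *reports*, so the table is a
  true partition of the database (`a+b+c+d = n`); this is the only
  reading under which the conservation invariant holds, and it is
  asserted for every screening row.
* **Multiplicity.** No multiple-testing adjustment: this is
  hypothesis-generating screening, recorded in the result metadata.

## Case selection

`select_cases()` first collapses duplicates, then applies the rules in a
fixed order — date window, reporter qualification, drug/role, event,
age, sex — attributing every rejected report to its *first* failing
rule, so the audit counts reconcile exactly
(`n_in - n_out = sum(rejected)`). Decisions taken where the design was
genuinely open:

* **"Single suspected or interacting drug"** is read as: the index drug
  has role suspected or interacting, and no *other* drug on the report is
  suspected. Two different suspected drugs therefore disqualify a report.
  The stricter reading is available via `allowed_roles = "suspected"`.
* **The date filter** applies to the report date (not reaction onset).
* **Age presence** is the criterion (any nonnegative value); no
  plausibility bounds.
* **Duplicate collapsing** replaces a probabilistic record-matching
  system with a deterministic key — country, sex, age rounded to whole
  years, sorted suspected-drug codes, sorted PT codes, report date —
  keeping the smallest report id. It is idempotent and recovers exactly
  the planted duplicates of the generator, which are exact-field copies
  (a declared simplification: real duplicates are fuzzy).

The event definition expands high-level terms (HLTs) to their PTs
through a MedDRA-like dictionary. The renal selection resolves, by
normalised name, seven HLTs under the renal/urinary SOC
(glomerulonephritis and nephrotic syndrome; nephritis NEC; nephropathies
and tubular disorders NEC; renal disorders NEC; renal failure and
impairment; renal hypertension and related conditions; renal vascular
and ischemic conditions); urological and infectious HLTs under the same
SOC are excluded. Because MedDRA is licensed, the bundled dictionary is
a small synthetic stand-in (invented codes, one HLGT layer, one
multi-parent PT, decoy terms); PT membership is taken as in-scope
regardless of which SOC path reaches it (multi-axiality is not
restricted).

## The synthetic generator

`generate_icsr_store()` draws, per report, one suspected drug from a
marginal distribution and each PT independently with probability
$q_P$; an injected signal $(D, P, \lambda)$ multiplies the inclusion
*odds* of $P$ by $\lambda$ for reports whose drug is $D$. Reports with
no reaction are redrawn. Under this model the population ROR of the
injected pair is exactly $\lambda$ and 1 elsewhere (`expected_ror()`):
conditioning on "at least one reaction" multiplies the event-negative
probability in both drug groups by the same factor (the chance of
carrying some *other* reaction), which cancels from the odds ratio as
long as at most one signal involves the queried PT. With several
overlapping signals the comparator group is slightly contaminated — the
familiar masking effect — and $\lambda$ becomes an approximation.

The default world (`default_synthetic_config()`): five index drugs at 2%
of reports each, nine comparator drugs sharing 90%; thirteen renal PTs
at rare inclusion probabilities (0.002–0.01, the screened grid) plus
eight common decoy PTs (nausea, headache, ...) so the zero-reaction
redraw stays mild; 10% consumer reporters, 5% missing age, 3% unknown
sex, 2% out-of-window dates and 2% planted duplicates, so each exclusion
rule has records to reject; a reporting window of 2001-11-07 to
2021-06-02. Demographics are cosmetic realism only (age truncated normal
64 ± 14 on [18, 100], 54% male, country and indication frequencies
loosely shaped like published cohort tables) and are never asserted
statistically. Each of these values was chosen once; tests do not tune
them.

What the generator does **not** emulate: reporting trends over time,
country reporting cultures, correlated reactions (syndromes),
notoriety/masking bias, fuzzy duplicates, partial dates. A green
recovery test therefore establishes that the pipeline correctly measures
the model it is pointed at — not that real-database estimates share
these properties.

## Validation strategy

* **Oracle equivalence.** `ror_ci()` is checked against (i) a frozen
  fixture computed once with an established external statistics library
  and (ii) an independently coded log-sum implementation, over all
  810,000 tables with cells 1..30, at 1e-9 relative tolerance.
* **Interval coverage.** 2,000 replicate databases (n = 50,000, one
  injected signal with $\lambda = 3$, signal PT at $q_P = 0.01$) are
  generated and the fraction of 95% intervals containing 3 is required
  to fall in [0.93, 0.97]. For speed, each replicate runs the
  generator's exposure-sampling core and skips the demographic
  decoration, which cannot affect the table; a dedicated test asserts
  that, at a fixed seed, the decorated store yields the identical 2x2
  table.
* **Signal recovery.** An injected $\lambda = 5$ pair at n = 100,000 must
  be flagged in at least 19 of 20 seeds; with no signals the SDR rate
  over the 5 × 13 grid stays below 10%.
* **Selection audit.** An eight-report hand fixture with one violation
  per rule yields exactly two cases with each rejection attributed to
  the correct rule.

## Descriptive summaries

`case_characteristics()` reports, per drug and overall: counts; age mean
and *sample* (n−1) SD; sex; ADR counts per renal HLT (a case counts once
per HLT reached by any of its reaction PTs, so a case may appear under
several HLTs; the denominator is the case count); seriousness; a
per-case outcome taken as the most severe reaction outcome (fatal >
recovered with sequelae > not recovered > recovering > recovered >
unknown); discontinuation (index drug withdrawn); top-k countries and
indications. Percentages round half-up to integers (`percent_int()`);
base R's round-half-even is deliberately not used. Published cohort
tables are not perfectly consistent under any single rounding rule
(e.g. a printed 39% for 557/1409 = 39.5%); the half-up convention is
kept and the discrepancy documented rather than special-cased.

`tto_summary()` pools times to onset (drug start to reaction onset,
whole days; negative intervals warn and count as missing) per
(drug, HLT) and reports linear-interpolation quantiles (R type 7) plus
mean and sample SD — published tables mix the two conventions, so both
are always exported and rendering chooses. Cells need more than
`min_display` (default 3, strict) cases to display, and more than one
observed TTO to be "known"; otherwise they render as `UNK`.

## Reproducibility

Every random draw is a pure function of a configuration that includes an
integer seed; seeds are threaded explicitly (`withr::with_seed`), never
left in global state. `run_pipeline()` writes a manifest (package and R
versions, seed, full configuration, artifact checksums) sufficient to
reproduce every artifact byte for byte.

## Known limitations

* The ROR is a screening statistic: it ranks reporting associations, not
  risks; confounding, notoriety bias and underreporting are untouched.
* The deterministic duplicate key misses fuzzy duplicates and can, in
  principle, collapse genuinely distinct reports that coincide on all
  key fields (vanishingly rare at realistic field cardinalities).
* `expected_ror()` is exact only for non-overlapping signals (see above).
* Partial dates are treated as missing; no imputation.
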