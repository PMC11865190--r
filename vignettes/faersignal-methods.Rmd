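---
title: "Methods: disproportionality signal detection on spontaneous report databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous report databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited reports of suspected drug reactions. They have no denominator
(the number of treated patients is unknown), so incidence cannot be
estimated; what can be estimated is *disproportionality* — whether a
drug–event pair is reported more often than the database background would
predict. `faersignal` implements the standard screening workflow for one
target drug: parse the quarterly ASCII tables, reduce the data to one clean
report per case, build a 2×2 table for every event, compute four
disproportionality statistics, and apply joint positivity criteria.

Every stage is validated against a bundled synthetic database generator
with *planted* relative-risk elevations, so the whole pipeline is testable
without downloading anything.

## Data reduction

**Deduplication.** A case may appear as several versions (same `caseid`,
different `primaryid`). We keep, per case, the version with the latest
receipt date, breaking ties by the numerically largest `primaryid`. This is
the standard FAERS practice; it is deterministic and idempotent, and the
counters satisfy retrieved − removed = retained.

**Drug-name normalization.** Raw drug strings are trimmed,
whitespace-collapsed and upper-cased, then mapped through a user-supplied
synonym table (RxNorm-derived in real use) by exact match. Fuzzy matching
is deliberately not offered: it is unauditable in a screening context.

**Primary-suspect filter.** A report enters the target set when at least
one of its drug entries maps to the target *and* carries role code `PS`.
Concomitant or secondary-suspect mentions do not qualify.

**Demographic summaries.** Each categorical panel (sex, age band, reporter
occupation, country, route) assigns every report to exactly one category,
with an explicit unknown class, so panels sum to the report total. Age
bands are half-open — [0,20), [20,40), [40,60), [60,∞) — and FAERS age
units (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`) are converted to years.
The **outcome panel is different**: its denominator is the number of
outcome *entries*, because one report may carry several outcomes. This
convention is forced by how published summary tables of this kind are
computed (the outcome shares sum to 100% only over entries) and is covered
by a dedicated test.

## Contingency tables

The counting unit is the report: a PT repeated within one report counts
once, and at SOC level the distinct (report, SOC) pairs are counted, so a
report with two nervous-system PTs contributes a single nervous-system
count. For each event `e` of a target drug:

|                | event `e` | other events |
|----------------|-----------|--------------|
| target PS      | a         | b            |
| all other reports | c      | d            |

with `N = a+b+c+d` the deduplicated universe and `E = (a+b)(a+c)/N` the
expected count under independence. The comparator is all-other-drugs — the
standard design for single-drug FAERS screens. PTs missing from the
PT→SOC map are reported as unmapped and excluded from SOC tables only.

## The four statistics

* **ROR** `= ad/(bc)`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, with a
  Yates-corrected χ²: per-cell `max(|O−E|−0.5, 0)²/E` (the floor keeps tiny
  deviations from contributing).
* **BCPNN information component** (bits), Bate's closed form with
  hyperparameters γ₁₁ = 1, α₁ = β₁ = 1, α = β = 2; `IC025 = E(IC) −
  1.96·√V(IC)`. The smoothing keeps everything finite, including at `a = 0`.
* **MGPS EBGM.** `a ~ Poisson(λE)` with a two-component gamma prior on λ.
  The five hyperparameters `(α₁, β₁, α₂, β₂, w)` are fitted by marginal
  maximum likelihood: marginally `a` is a mixture of negative binomials,
  and the summed log-likelihood is maximized on log/logit scales with
  multi-start optimization (the default prior `(0.2, 0.1, 2.0, 4.0, 1/3)`
  plus four deterministically jittered starts, Nelder–Mead then BFGS,
  1e-8 relative tolerance). Mixture likelihoods are multimodal; the default
  prior is always a candidate, so the attained likelihood never falls below
  it. With fewer than 50 usable tables the default prior is returned with a
  `fallback` flag. The posterior is again a two-gamma mixture;
  `EBGM = 2^{E[log₂ λ]}` via `ψ(α+a) − ln(β+E)` per component, and `EBGM05`
  is the posterior 5th percentile found by root-finding on the mixture CDF
  (bracket widened geometrically). A `simple` mode
  (`EBGM = aN/((a+b)(a+c))`, `EBGM05 = exp(ln EBGM − 1.645·√(1/a+…+1/d))`)
  is offered because the ratio-based variant is common in FAERS screening
  papers; the MGPS mode is the default.

**Joint signal criteria** (all must hold): ROR ≥ 3 with CI lower bound > 1,
PRR ≥ 2 with CI lower bound > 1, IC025 > 1, EBGM05 > 2, and `a ≥ 3`.
The IC025 > 1 floor is stricter than the conventional IC025 > 0 screen;
the conventional rule is one `signal_thresholds(ic025_min = 0)` away.

**Numerical policies.** No continuity correction: zero cells suppress the
frequentist estimates (with a reason code) rather than silently biasing
them; `min_count = 3` makes `a = 0` moot, and zero `b`, `c` or `d` is
pathological at screening scale. Counts below `min_count` are reported with
their cells but no estimates. Ranking is a stable descending sort with ties
broken by `a`, then event label. Whether the SOC-level prior is fitted at
SOC level or reused from PT level is configurable (`prior_fit_level`);
the default fits per level, accepting that a handful of SOC tables will
trigger the documented default-prior fallback.

## Time to onset and stratification

Onset = event date − earliest target-drug therapy start, in whole days,
using full-precision (`YYYYMMDD`) dates only. Partial dates are *excluded,
not imputed*: imputing (say) day 15 into month-precision dates would
inflate the early bins, which carry the headline claim that most events
occur within days of starting therapy. Negative onsets are excluded too;
all exclusions are tallied. Bins are `<3 d` (0–2), `3–7 d` (3–7),
`1–2 wk` (8–14), `2 wk–1 mo` (15–30), `>1 mo` (≥31) — the textual labels
read as inclusive of their stated endpoints.

The gender-stratified volcano rebuilds every contingency table against the
stratum's own universe (male-stratum N + female-stratum N + unknown =
total N), attaches a two-sided Fisher exact p-value to each 2×2 (exact at
small counts, the natural choice for a screen the source analysis leaves
unnamed), adjusts with Benjamini–Hochberg within the stratum, and flags
pairs with adjusted p < 0.05 and `a ≥ 3`. Note that BH adjustment is a
one-shot transform: re-adjusting already-adjusted p-values is not a no-op
in general (e.g. `p = (0.02, 0.5)` → `(0.04, 0.5)` → `(0.08, 0.5)`), so
the tests assert step-up correctness, stability and monotonicity rather
than functional idempotence.

## The synthetic generator

`generate_dataset()` emits the six FAERS-dialect tables plus toy synonym
and PT→SOC tables. What it emulates, and the defaults it uses:

* **Case structure**: multi-table records keyed by `caseid`/`primaryid`,
  with `round(duplicate_rate × n_reports)` cases emitted twice as a
  superseding later version. Default `duplicate_rate = 0.18`, the
  removed-to-retained ratio seen in full-database deduplication.
* **Composition**: demographic category probabilities are the printed
  marginal composition of a real single-drug extract (e.g. sex
  1026/1490/58 over 2574 reports; outcome codes over 3299 entries);
  reports carry 2.5 reactions on average (≈ 6605 reactions / 2574
  reports) and 2 drug mentions; onset days are geometric with mean 4, so
  roughly half of onsets fall within the first two days and the first two
  bins dominate, matching the qualitative published pattern.
* **Dates**: receipt and therapy-start dates uniform over 2004–2023 (so
  yearly trend curves are exercised); event = start + onset. With
  probability `missing_date_rate` (default 0.2) a start/event date is
  truncated to `YYYYMM` or `YYYY`, exercising the partial-date policy.
  Receipt dates stay full because deduplication orders on them.
* **Planted signals**: for a report containing a planted drug, each
  planted event's mention weight is multiplied by the largest planted
  relative risk among the report's drugs and the weight vector
  renormalized. This makes the planted RR the asymptotic reporting ratio
  of the pair (up to the renormalization factor `1 + p(RR−1)`, which is
  small when planted events are rare). Configs whose planted probability
  mass exceeds 1 for some drug are rejected. A switch can bias one
  event's sex ratio for stratified tests.
* **Determinism**: a fixed seed gives byte-identical files; the RNG state
  of the calling session is left untouched.

What it does **not** emulate: report-level covariance between drugs
(polypharmacy), country- or reporter-specific reporting cultures,
MedDRA's real hierarchy (toy PT/SOC labels only), and secular trends in
reporting volume. Demographics are independent of drug and event
assignment unless the sex-bias switch is used — which keeps null data
genuinely null for false-positive-rate tests, at the cost of realism.
Passing the recovery tests therefore shows the *pipeline arithmetic* is
right, not that real-database confounding (indication bias, stimulated
reporting, duplicates that survive deduplication) is handled.

## Problem sizes used in validation

The test-and-validation workload was sized once: recovery runs use
50,000-report databases with 20 planted pairs spanning relative risks
1–20 over 20 replicate seeds, qualifying a pair for the sensitivity
denominator when its true RR ≥ 10 and its expected count (computed from
the generator mechanism) is ≥ 20; null behavior uses an unplanted
50,000-report database across all 50 drugs; formula-level oracle checks
use 1,000 random tables with cells 1–500; the shrinker's prior-recovery
check simulates 5,000 pairs from the default prior and compares held-out
predictive log-likelihood within 1%; the observed-to-expected recovery of
a single planted pair is checked on a 1,000,000-report in-memory database
where a rare single-drug configuration makes `a/E` a clean estimate of
the planted RR. Corpus-scale published signal values (hundreds of
millions of reports across 80 quarters) are out of reach by design;
planted-truth recovery is the substitute evidence.

## Known limitations

* Exact-match synonym normalization means unmapped spellings silently
  become their own "drug"; the normalized name column makes this auditable.
* The MGPS fit labels its components arbitrarily (the mixture is
  exchangeable); downstream quantities are label-invariant.
* SOC-level universes are small (dozens of classes), so the per-level
  prior fit usually falls back to the default prior — flagged, by design.
* Fisher p-values in the volcano use the exact conditional test; at very
  large margins a mid-p or unconditional test would be less conservative.
  Conservatism is acceptable in a screen whose output is a shortlist.
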