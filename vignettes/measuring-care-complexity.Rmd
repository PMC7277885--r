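---
title: "Measuring care complexity and auditing patient allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring care complexity and auditing patient allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecomplexity)
```

## The model

Intensity-of-care hospital organization assigns beds to four tiers —
sub-intensive, high, medium and low care — and presumes each patient
occupies the tier their needs call for. Needs have two distinct, co-present
components: *clinical instability* (acute physiological derangement) and
*care dependence* (quantity and intensity of required nursing work). This
package operationalizes both and combines them:

1. **NEWS.** Each vital-sign observation is scored against a band table:
   respiration rate, SpO₂, temperature, systolic blood pressure and heart
   rate each contribute 0–3 points, consciousness (AVPU) contributes 0
   (alert) or 3 (anything less), and supplemental oxygen adds a flat 2.
   The total (0–20) maps to a band: stable 0–4, unstable 5–6, critical ≥ 7.
2. **mICD.** Eight nursing-care dimensions each rated 1–4 by the assessor;
   the total (8–32) maps to low / average / high dependence.
3. **ICC.** A 3 × 3 matrix crosses the two classes into a Low / Medium /
   High complexity class. The shipped matrix returns Low only for
   (stable, low) and High whenever the patient is critical or
   high-dependent.

The analysis unit is the **patient-day**. Instability is re-observed daily
(the daily *maximum* NEWS total is used, because instability is an
excursion process and the day's worst observation is what drives
escalation); dependence is assessed at admission and re-assessed only on
setting transfer, so a day's mICD is the most recent assessment at or
before it. The allocation audit then asks, per setting, what fraction of
patient-days carry the complexity class that setting is intended for
(sub-intensive and high → High, medium → Medium, low → Low; the mapping is
an argument, so alternative policies can be evaluated).

### Assumptions and caveats

* **Days are treated as independent units** in the cross-tabulations and
  chi-square tests. Days within one hospitalization are of course
  correlated; the per-day analysis is an occupancy description, not an
  inferential model of patients, and p-values on day-level tables should be
  read accordingly. This is a deliberate reproduction of standard practice
  in allocation audits, not an endorsement.
* The per-patient analysis avoids this by using one row per
  hospitalization, classed by admission-day complexity.
* The NEWS band table is an instrument constant, not a fitted object. The
  shipped default is the Royal College of Physicians (2012) banding; local
  variants load from YAML and are validated (disjoint adjacent intervals
  covering the sanity range, strictly increasing band cutpoints).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Band table | RCP NEWS 2012 | — | The instrument in routine Italian medical-area use; swappable via `read_news_bands()` |
| Stable band | totals 0–4 | points | A total of 0 is attainable and must classify; the band therefore starts at 0 |
| mICD cutpoints | `text_bands` 8–14 / 15–23 / 24–32 | points | The scheme the ICC matrix is keyed to; `table8_bands` (8–16 / 17–25 / ≥ 26) is selectable because both schemes circulate for this instrument and published tabulations exist under each |
| ICC matrix | see README | — | Localizable YAML; monotonicity along both axes is enforced, so "higher inputs, higher complexity" is a structural guarantee |
| Sanity bounds | RR 0–80, SpO₂ 50–100, T 25–45 °C, SBP 30–300, HR 0–300 | clinical units | Values outside are data errors, not extreme scores |
| Consistency mapping | sub-intensive → High, high → High, medium → Medium, low → Low | — | The allocation hypothesis under audit; overridable |
| Missing vitals | `strict` | — | Retrospective records are incomplete; `carry_forward` reuses the previous day's maximum and reports the fill count, but silence is never the default |

Numerical conventions: band intervals are closed on their printed
endpoints; temperature is compared after rounding to 0.1 °C and all other
parameters to integers, so the printed intervals tile the measurement
resolution exactly. Printed percentages round half *up* to one decimal
(base R rounds half to even, which published clinical tables do not).
Chi-square tests are Pearson without continuity correction; rows or
columns with zero margin stay in the counts but are dropped from the test,
and any expected cell below 5 raises a classed warning. Kruskal–Wallis uses
midranks with the tie correction; the Shapiro–Wilk normality check warns
outside its 4 ≤ n ≤ 2000 validity range but still returns the statistic
where computable.

## The synthetic cohort generator

No patient-level records are deposited for populations of this kind, so
the generator is a first-class module: it emulates the *statistical
structure* of a reference medical-area population — 450 hospitalizations
(internal medicine 349, neurology 39, pneumology 62) totalling exactly
2884 patient-days — from published marginal tabulations:

* ward-conditional gender, five-class age, four-class length-of-stay,
  care-setting and nine-category discharge-outcome weights (the printed
  per-ward counts, normalized). Only internal-medicine patients can occupy
  low care, as observed;
* setting-conditional mixes over instability bands and dependence levels
  (the printed per-setting day counts, normalized).

### Latent-first realization

The generator samples the *class* first and realizes concrete data inside
it: a day's latent band picks a target total (uniform over the band's
total range), the total is decomposed into admissible component scores,
and each parameter value is drawn uniformly from the band-table region
carrying that sub-score. Dimension levels are realized the same way for
the mICD. Re-scoring realized data therefore recovers the latent class
*exactly, by construction* — the round-trip the test suite asserts on every
day of every seeded cohort. Critical-band days draw target totals from
7–12 rather than the theoretical 7–20: ward patients above the low teens
are vanishingly rare, and capping the tail keeps realized vitals
clinically plausible. For the same reason, unbounded printed intervals are
clipped to plausible ranges before sampling (RR 4–40, SpO₂ 75–100,
T 32–41.5 °C, SBP 60–260, HR 30–180).

### Design choices that were genuinely open

* **Copula.** Only the *marginal* per-setting mixes of bands and levels
  are published; their joint distribution is not. The generator samples
  them independently given the setting, and this is an explicit
  configuration point (degenerate marginals pin the joint exactly, which
  is how the consistency tests construct allocation-consistent cohorts).
* **Day counting.** One row per calendar day from admission (inclusive) to
  discharge (exclusive); a one-day stay is `discharge = admission + 1`.
  This makes patient-days additive (the conservation property in the test
  suite) and removes zero-length intervals from the data model.
* **Exact day total.** Sampled lengths of stay are repaired to the
  configured cohort total by random unit decrements/increments
  (`repair_total_days()`), preserving the class structure approximately
  while making the only printed day total exactly reproducible under any
  seed.
* **Within-stay transfers.** A stay of ≥ 2 days has one mid-stay setting
  transfer with probability 0.15 — chosen once to match the order of
  magnitude of the "exchange" of patients the reference population shows —
  with a dependence re-assessment at the boundary, exercising the
  transfer machinery end to end.
* **Allocation mismatch.** `mismatch_rate = m` re-assigns each patient-day
  independently with probability *m* to a setting inconsistent with that
  day's complexity class (uniform over inconsistent settings), then
  rebuilds setting intervals as maximal runs. On an otherwise consistent
  cohort the audit recovers 1 − *m* up to binomial error, which the test
  suite checks at the full 450-patient scale. The default configuration
  uses *m* = 0: its per-setting severity mixes already embody the
  allocation inconsistency observed in the reference population, so no
  extra mismatch should be injected on top.
* **Seeding.** One root seed spawns four fixed streams (patients → days →
  vitals → dimensions), so extending one stage cannot shift draws in
  another; identical config + seed reproduces the cohort bit for bit.

### What the generator does not emulate

Admission dynamics (arrival processes, bed occupancy, seasonal census),
within-patient temporal correlation of vitals (days are exchangeable given
setting), comorbidity structure, and any linkage between severity and
outcome (outcomes are drawn from ward-conditional weights, independent of
the severity path). Passing tests on synthetic cohorts therefore
demonstrate the *pipeline's* correctness — scoring, expansion, tabulation,
consistency accounting — and distributional calibration to the configured
mixes; they do not validate the instruments clinically, and effects that
live in the unmodelled structure (e.g., severity-conditional mortality)
cannot be studied on the default generator.

## Problem sizes and determinism in the shipped tests

The suite exercises the full 450-patient / 2884-day configuration where
the property demands that scale (exact size reproduction, mix calibration,
consistency recovery) and 20–40-patient cohorts elsewhere; property loops
run under fixed seeds. Published-table reproduction uses the printed day
counts as fixtures and asserts only internally consistent cells: in the
instability-by-setting table the unstable column total as printed
disagrees with its own column sum (422 vs 426) and one row's percentages
are inconsistent with its counts, so assertions pin the stable and
critical column totals (2247, 215) and the low-care critical cell (16.8%),
plus the dependence table's fully consistent grand-total row
(1436 / 1198 / 250 = 49.8 / 41.5 / 8.7%).

## Known limitations

* The chi-square and Kruskal–Wallis statistics of the original cohort are
  not reproducible from any deposit — they depended on undeposited raw
  records — and are out of scope; the package reproduces the *method* and
  the internally consistent printed tabulations.
* The two mICD cutpoint schemes are irreconcilable from the published
  material; defaulting to `text_bands` (the matrix's ranges) is a
  judgement, and analyses sensitive to the boundary totals 15–16 and 24–25
  should be run under both schemes.
* `carry_forward` imputation is last-observation-carried-forward within a
  stay; it cannot fill a missing first day and biases toward stability by
  construction. It exists to make incomplete retrospective records
  analyzable, loudly.
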