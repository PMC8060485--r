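---
title: "Quantifying cortical venous filling from dynamic CTA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical venous filling from dynamic CTA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvftools)
```

## The problem

In patients with severe unilateral stenosis or occlusion of the middle
cerebral artery (MCA) M1 segment, venous drainage of the MCA territory is a
marker of how well the downstream circulation copes with the upstream lesion.
Dynamic CT angiography acquires a series of whole-brain volumes (19 in the
protocol modelled here) after a contrast bolus, giving each vascular
structure a time–attenuation curve (TAC): attenuation in Hounsfield units
versus acquisition time. From the TACs of the three cortical veins draining
the MCA territory — the superficial middle cerebral vein (SMCV), the vein of
Trolard (VOT) and the vein of Labbé (VOL) — together with the MCA and the
superior sagittal sinus (SSS), this package quantifies two aspects of
cortical venous filling (CVF):

* **velocity** — when the veins of each hemisphere begin to fill, reach peak
  opacification, and clear, and how much later the affected hemisphere is
  than the contralateral one;
* **extent** — which veins never opacify at all (CVF−), and in particular
  the *ipsilateral* CVF− pattern (absent on the affected side while present
  contralaterally), which separates lesion effects from anatomical
  variation.

The cohort-level layer then relates these scores to collateral status and
3-month outcome with the usual clinical-epidemiology toolkit (2×2 odds
ratios with Woolf intervals, chi-square/Fisher/Mann–Whitney comparisons,
logistic models).

## Timing model

All times are reported **on the acquisition grid**: no sub-sample
interpolation is performed, matching how such studies read volume-indexed
times. The per-hemisphere time points are:

* `CVF1` — earliest grid time at which *any* present vein's
  baseline-corrected enhancement reaches the visibility threshold;
* `CVF2` — earliest grid time at which *most* present veins are within a
  tolerance of their own maximum enhancement;
* `CVF3` — earliest grid time after `CVF2` at which *every* present vein has
  dropped below the threshold again.

Derived intervals are `CVF21 = CVF2 − CVF1` (early-to-peak venous phase) and
`CVF31 = CVF3 − CVF1` (whole venous phase); relative scores
(`rCVF1` … `rCVF31`) are affected minus contralateral, so positive values
mean delayed filling on the affected side. Velocity is dichotomized at the
analysis cohort's sample median, with values *equal to* the median labelled
fast; the thresholds are computed within the symptomatic group, because
that is the cohort in which velocity is related to collaterals and outcome.

Three numerical choices deserve a note:

* **Visibility threshold, 50 HU above baseline.** The original judgement is
  visual; a single threshold shared by onset, clearance and presence keeps
  the scoring auditable. 50 HU is ten standard deviations above the default
  5 HU simulation noise, so detection is stable (the tests confirm zero
  presence misclassifications in 1000 noisy veins).
* **"Most veins" for CVF2** is operationalized as at least 50% of present
  veins within 5% of their own maxima, taking the earliest such time. For a
  single vein and zero tolerance this degrades to the argmax. For three or
  more veins with disjoint near-peak windows no grid time may satisfy the
  majority rule; the implementation then returns the earliest time
  maximizing the near-peak count, a deterministic tie-down of a case the
  rule leaves undefined.
* **Censoring is explicit.** A hemisphere whose veins never reach the
  threshold raises a censored-onset condition, and veins still opacified at
  the last volume raise censored clearance; the cohort scorer records these
  as flags with `NA` times rather than fabricating values. Absent (CVF−)
  veins are excluded from all three detections — a never-filling vein would
  otherwise censor every patient who has one.

Phase selection follows the protocol's reading: the venous phase (V-TAC) is
the SSS enhancement peak; the arterial phase (A-TAC) is the pre-venous grid
time maximizing the *minimum* of the two MCA enhancements — a deterministic
surrogate for "best opacification of the bilateral MCA, least affected by
veins" — with ties broken toward the earlier time.

## Extent model

A vein is present (CVF+) if it reaches the threshold at any grid time in the
venous window, absent (CVF−) otherwise. The venous phase has no numeric
boundaries in the visual protocol; here the window runs from one grid
interval before the hemisphere's `CVF1` to the last volume, falling back to
two intervals before V-TAC when timing is censored. Because `CVF1` is the
earliest crossing among present veins, the window always contains every
crossing, and the two-pass scheme (provisional presence on the fallback
window, timing, then confirmation on the `CVF1`-anchored window) is
self-consistent. A vein absent on *both* sides is attributed to anatomical
variation and does not count toward ipsilateral CVF−; the count category
CVF−=3 is representable even though cohorts may never exhibit it.

## Flow and collateral rules

The image readings behind these rules (a filling ratio, three-level
collateral grades at each phase) enter as data — simulated or transcribed
from a reader — and only the decision rules are computed: antegrade flow is
preserved when the affected-side MCA filling exceeds two-thirds of the
contralateral side (*strictly* — exactly 2/3 is compromised, since the
criterion is "more than two-thirds"), and collateral status is good exactly
when either phase shows complete enhancement.

## Statistical layer

Odds ratios are cross-products with the Woolf log-normal interval,
`exp(log OR ± z √(1/a + 1/b + 1/c + 1/d))`; a zero cell triggers the
Haldane–Anscombe correction (0.5 added to every cell, method flagged). This
reproduces the published interval endpoints from the printed counts. The
2×2 association test defaults to an auto mode — Fisher's exact test when
any expected count is below 5, Pearson's chi-square otherwise — because the
printed p-values are consistent with no single test choice; every mode is
also available explicitly. Two-sample comparisons use the pooled-variance t
or the Mann–Whitney U (exact by enumeration when the pooled sample is at
most 10 and tie-free, normal approximation with tie correction otherwise).
Logistic fits are maximum likelihood via iteratively reweighted least
squares (tolerance 1e-8, 100 iterations) with Wald intervals; separation or
non-convergence raises an error carrying the iteration count rather than
returning divergent estimates.

Two orientation quirks of the published outcome table are reproduced as
printed rather than harmonized: the NIHSS odds ratio treats *poor* outcome
as the event, while the two-vein-absence odds ratio is the cross-product
with *good* outcome as the case row (its interval endpoints, not the
rounded point estimate, are the reproducible surface). Percentages print
with half-away-from-zero rounding (8/22 → "8 (36%)"). The within-patient
hemisphere comparison uses the paired Wilcoxon signed-rank test; the source
tables name only unpaired tests, but affected-versus-contralateral times
are paired by construction. No multiplicity correction is applied anywhere,
matching the original analysis.

## The synthetic cohort

No per-patient data accompany the study this package models, so the
generator is the test bed. It emulates:

* gamma-variate bolus curves `baseline + K (t − t0)^α e^{−(t−t0)/β}` for
  arteries, veins and the SSS, sampled on the 19-volume grid with Gaussian
  noise (5 HU default). The default grid is 2.0 s spacing from 8.0 s; the
  acquisition interval is not stated in the protocol, but the printed case
  timings (e.g. onsets 1.9–2.0 s apart) are consistent with ≈2 s;
* group-specific affected-side delays: the onset delay δ₁ (log-normal,
  medians 2.0 s symptomatic / 1.8 s asymptomatic) and the early-to-peak
  widening δ₂₁ (shifted log-normal, medians 1.9 s / 0.1 s, with a negative
  tail because observed relative intervals can be negative);
* per-vein, per-side absence probabilities taken from the published
  hemisphere table, which imply ipsilateral CVF− proportions of about 53%
  (symptomatic) and 18% (asymptomatic) without further tuning;
* probabilistic links: poor collateral status with probability 0.58 given a
  truly fast δ₂₁ versus 0.18 given slow (the published cross-table rates),
  and poor 3-month outcome with probability rising in the true ipsilateral
  CVF− count (0.12 / 0.25 / 0.86 for counts 0 / 1 / 2+).

The injected delays live on the *observable* scale. Widening β alone also
slows the rising limb, which moves the visibility crossing later and would
attenuate the measured early-to-peak widening. For a peak-normalized
gamma-variate the threshold crossing is `β·u` where `u` solves
`(u/α)^α e^{α−u} = threshold/amplitude`, so both the analytic onset
(`t0 + β·u`) and the early-to-peak interval (`β·(α − u)`) are linear in β.
The affected vein therefore uses `β' = β + δ₂₁/(α − u)` with `t0` pulled
back by `(β' − β)·u`: the analytic rCVF1 and rCVF21 equal δ₁ and δ₂₁
exactly, and scored values differ only by grid discretization (at most one
spacing). This is what makes parameter recovery a meaningful end-to-end
test.

What the generator does **not** emulate: image-space effects (partial
volume, beam hardening, motion), deep venous drainage, correlated vein
absences, reader disagreement, or any within-patient correlation between
delays and absences beyond the links above. Passing tests therefore
demonstrate that the scoring pipeline recovers what the data model encodes
— not that the thresholds would be optimal on real scanner data.

## Problem sizes used in the shipped checks

The packaged tests generate cohorts at the study size (36 + 22) for
direction checks, 200 + 200 noiseless patients for parameter recovery,
1000 veins for presence calibration, and 2000 null replicates for the
t-test's type-I error; these sizes give stable medians and rates while
keeping a full run in the tens of seconds.

## Worked example

```{r example}
affected <- hemisphere_cvf(20.9, 24.8, 37.7)
contralateral <- hemisphere_cvf(19.0, 24.8, 32.7)
relative_cvf(affected, contralateral)

odds_ratio_woolf(11, 3, 8, 14)   # fast/slow early-to-peak vs collaterals
```

A negative `rcvf21` with positive `rcvf1`/`rcvf3`, as here, means the
affected hemisphere started late but condensed its early-to-peak phase —
one of the patterns that motivates scoring the intervals and not only the
onsets.

## Known limitations

* Times are grid-quantized; with 2 s volumes, any effect smaller than the
  spacing is invisible patient-by-patient and only recoverable in medians.
* The CVF2 majority rule is one of several defensible readings of "most
  veins"; the tolerance (5%) and fraction (50%) are exposed as arguments.
* The velocity split inherits the instability of sample medians in small
  cohorts; thresholds are reported alongside every classification.
* Censored clearance is flagged but the affected intervals are simply `NA`;
  no survival-style handling is attempted.
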