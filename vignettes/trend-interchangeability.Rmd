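---
title: "The trend interchangeability method: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The trend interchangeability method: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendim)
```

## The question the method answers

Two devices measure the same physiological quantity — say cardiac output —
on the same patients at the same times: an accepted reference method (RM)
and a candidate test method (TM). For bedside decisions what matters is
often not the agreement of single readings but whether a *change* reported
by the test method can stand in for the change the reference would have
shown. The trend interchangeability method (TIM) answers this per change,
using one input besides the data: the reference method's repeatability
coefficient RC, the multiplicative fraction such that a repeat measurement
of an unchanged quantity is expected within `value ± value·RC`.

## The two-step classification

Each unit of analysis is a change between consecutive paired measurements,
`(RM₁, TM₁) → (RM₂, TM₂)`.

**Step 1 — interpretability.** The change is classified `uninterpretable`
when the precision intervals `RM₁ ± RM₁·RC` and `RM₂ ± RM₂·RC` overlap:
the reference method cannot distinguish the two readings from repetition
noise, so no statement about the test method is possible. The test values
are never consulted in this step. Intervals that touch at a single
boundary point count as overlapping — interpretability should not be
claimed from a measure-zero separation.

**Step 2 — interchangeability.** For an interpretable change, two lines
anchored at the first pair bound the set of second pairs whose implied
change is consistent with the reference change up to repeatability. With
`X` the reference-axis and `Y` the test-axis coordinate of the *second*
pair,

$$X = Y(1+RC) + (1+RC)(RM_1 - TM_1), \qquad
  X = Y(1-RC) + (1+RC)(RM_1 - TM_1).$$

Evaluating both lines at `Y = TM₂` gives a closed interval on the
reference axis. If `RM₂` lies inside it the change is `interchangeable`;
if `RM₂` is outside but its own precision interval `RM₂ ± RM₂·RC`
(taken along the reference axis at fixed `Y = TM₂`) still reaches the
zone, the change sits in the `gray_zone`; otherwise it is
`noninterchangeable`.

The per-device summary counts the four categories and reports the trend
interchangeability rate: interchangeable changes over interpretable ones
(total minus uninterpretable; gray-zone changes are interpretable and so
dilute the rate). The rate is graded excellent (≥ 95%), good (≥ 90%),
poor (75–90%) or not clinically relevant (< 75%), and a Pearson chi-square
on the devices × (interchangeable, not) table tests homogeneity across
devices.

### Conventions the published description leaves open

Several details are not fixed by the published description; the package
fixes them once and documents them here.

* **Axis convention.** `X` is the reference-method coordinate and `Y` the
  test-method coordinate of the second pair. This is the only reading
  under which a test method identical to the reference classifies as
  interchangeable for every interpretable change (with `TM ≡ RM` the
  offset term vanishes and the zone at `Y = RM₂` is
  `[(1−RC)·RM₂, (1+RC)·RM₂]`, which always contains `RM₂`). The package
  treats this identity oracle as load-bearing and tests it.
* **Gray-zone interval.** The "precision interval of the second point" is
  attached to the reference coordinate `RM₂`, as a segment along the
  reference axis at fixed `Y = TM₂`: repeatability is a property of the
  reference method, and the screen in step 1 already treats it that way.
  Attaching it to the test coordinate instead would make the gray zone
  depend on the test method's precision, which the procedure never
  quantifies.
* **Asymmetric intercept.** As published, the `(1−RC)`-slope line carries
  the same `(1+RC)` intercept factor as the upper line. The package
  implements exactly that by default and offers
  `symmetric_intercepts = TRUE` for the plausibly intended `(1−RC)`
  factor. The difference is consequential: with the published intercepts,
  adding a constant offset `c` to every test reading shifts the lower
  zone bound by `−2·RC·c`, so the classification is exactly invariant to
  constant test-method bias only in the symmetric variant (for positive
  bias the published zone is slightly more permissive). Either way a
  purely additive test-method bias does **not** destroy trend
  interchangeability — the anchor term `(RM₁ − TM₁)` absorbs it. What
  degrades the rate is noise or non-constant bias in the test method.
* **Closed region.** Points exactly on a line are inside; all boundary
  comparisons use a relative tolerance of 1e−9, far below any
  physiological resolution, so floating-point jitter cannot flip a
  category.
* **Non-positive measurements.** The precision interval uses `|value|·RC`
  so `lo ≤ hi` always; a warning is raised because the multiplicative
  geometry is motivated by positive quantities (simulated test readings
  can dip below zero).

## Data handling

`read_series()` ingests long-format delimited text (one row per subject,
device and time; configurable column mapping and delimiter) and applies
two exclusion rules, logging every dropped row with a reason:

* rows with a missing reference or test value are dropped, and no change
  is ever built *across* the gap — both changes touching the missing pair
  are lost;
* with `drop_first = TRUE` (the default when reading files) the first
  pair of every subject–device series is dropped, for designs where the
  first simultaneous measurement calibrates the test device. For
  in-memory and simulated data the default is `FALSE`, since a simulated
  series has no calibration reading; a 150 × 3 design then yields the
  full 300 changes.

Each test device is classified independently against the shared reference
column; because step 1 uses only the reference values, the uninterpretable
count is identical across devices measured at the same times.

## The synthetic study design

`tim_design()` emulates a monitor-validation cohort: 150 patients, 3
paired values (2 changes) each, patients assigned in equal thirds to
value ranges centred at 2.5, 3.5 and 5 units. Each patient's six values
(reference and test at three times) are one multivariate-normal draw.
The published description of the reference dataset leaves the
variance–covariance matrices unreadable, so the defaults here are a
reconstruction, chosen once: per-range standard deviations of 1.5, 1.2
and 1.0 units (decreasing with the range centre, following the stated
design), a within-time correlation of 0.9 between reference and test
readings (paired monitors track the same physiology closely), and an
across-time correlation of 0.2 (hemodynamic state changes substantially
between the predefined measurement times, which is what makes large
changes common). The three building blocks combine as a Kronecker
product, guaranteeing a valid covariance matrix. These choices put the
pooled mean near 3.67 units and give the wide pooled span and large
changes characteristic of the reference dataset; they are *not* the
original matrices, so category counts on generated data resemble, but do
not exactly reproduce, the published ones — exact-count checks are
reserved for the original supplementary fixtures when those files are
available locally.

What the generator does not emulate: repeated calibration, drift or
heteroscedastic device noise within a patient, serial correlation beyond
one common level, or missingness. Passing property tests on generated
data therefore demonstrates the correctness of the classification
machinery, not the field performance of any device.

`simulate_biased()` provides controlled scenarios (`tm = rm + bias +
noise`) for the identity oracle and degradation properties described
above.

## Legacy comparators

For side-by-side reporting the package includes the two classical
trending statistics. The four-quadrant `concordance_rate()` counts
changes where both methods move in the same direction, after an optional
central exclusion zone; a change is excluded when *both* |ΔRM| and |ΔTM|
fall below the threshold. No exclusion is applied by default — published
thresholds are arbitrary — and a percentage threshold is interpreted
relative to the mean absolute change magnitude, a package convention that
keeps the rate invariant under rescaling (a bare change pair carries no
instrument scale for a percent-of-reading rule to use). `to_polar()` and
`polar_stats()` give the polar-plot view: each change is a vector whose
angle is measured from the line of identity, summarised by the angular
bias (mean) and radial limits of agreement (1.96 SD) against the
customary ±5°/±30° thresholds. Vectors in the lower-left half-plane —
both methods decreasing — are folded through the origin by default
(`fold = FALSE` disables this), since a concordant decrease should read
like a concordant increase; plain rather than circular moments are used
because the thresholds presuppose angles clustered near zero.

A four-change didactic set in the test suite shows why the comparison
matters: all four changes are concordant and inside the ±30° radial
limits, yet receive four different interchangeability categories.

## Numerical and degenerate-input behaviour

* Undefined ratios are `NA` and flagged, never 0: the TIM rate with no
  interpretable change, the concordance rate with everything excluded,
  polar statistics with fewer than two surviving vectors.
* Devices with no interpretable change are excluded from the chi-square
  with a warning; at least two must remain.
* Changes with a missing member are excluded records, not classifications.
* All simulation is reproducible from the design's integer seed.

## Problem sizes

The test suite validates the classifier against an independent
brute-force implementation (direct evaluation of the two published
inequalities, gray-zone membership by dense 2001-point sampling of the
precision interval) on 10,000 random quadruples, and exercises the
invariants (identity oracle, monotone screening in RC, positive-scale
invariance, partition and denominator arithmetic) on hundreds to
thousands of randomised cases under fixed seeds; the full default design
(150 patients) is used for the qualitative repeatability contrast —
raising RC from 5% to 20% converts noninterchangeable changes into
uninterpretable ones.

## Limitations

* RC is assumed constant over time and across the measurement range;
  range-dependent repeatability is not modelled.
* No confidence interval is attached to the TIM rate; none is defined
  for the procedure.
* Uninterpretable changes are reported, not reweighted or reclassified;
  overlap-weighted reinterpretation is out of scope.
* The clinical grading thresholds (95/90/75%) are conventional labels,
  not decision theory.
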