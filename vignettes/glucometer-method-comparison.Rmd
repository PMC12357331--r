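---
title: "Methods: stratified glucometer method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified glucometer method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucobench)
```

# The problem

Neonatal hypoglycemia must be detected quickly, but analyzers validated for
newborns are costly and scarce where preterm birth rates are highest. Adult
point-of-care (POC) glucometers are cheap and ubiquitous — yet they were
validated for adult glucose ranges and near-normal adult hematocrit, while
neonatal samples combine low glucose (a clinically relevant hypoglycemic
threshold near 40 mg/dL) with hematocrits anywhere from ~18% (anemia of
prematurity) to ~55%+ (normal term polycythemia). Strip-based meters measure
whole-blood glucose and convert to plasma-equivalent values assuming a
normal adult hematocrit, so both tails of the hematocrit range distort their
readings.

`glucobench` analyzes the standard bench design for this question: whole
blood adjusted to each hematocrit × glucose stratum, measured in replicate
on every candidate meter and on a laboratory reference analyzer, across
multiple donor days. The package takes the long-format measurement records
and produces the accuracy/precision summaries, guideline banding, error-grid
zoning, device-error accounting and final device grouping.

# The analysis model

## Reference truth is per day and per condition

It is not possible to prepare identical samples on different donor days, so
the analysis never compares across days: for each condition on a given day,
the truth is the arithmetic mean of that day's reference replicates
(nominally five), and every meter reading is expressed as a signed percent
deviation from *its own day's* truth,

$$d_i = 100 \cdot \frac{m_i - \bar t}{\bar t}.$$

Strata are keyed by the *nominal* targets (18/40/55% hematocrit ×
40/150 mg/dL glucose by default); realized levels (measured hematocrit, the
day's realized glucose) are carried as metadata, absorbed by the per-day
truth. Reference replicates shared by several meters reading from the same
blood drop are deduplicated before averaging. A replicate-order drift check
(`truth_drift_check()`) guards the assumption that glycolysis was
sufficiently suppressed during a run: it reports the slope of reference
value against replicate index and flags groups whose first-to-last change
exceeds a threshold (default 5% — an invented but conservative default,
configurable, since "no relevant drift" is a qualitative judgement).

## Error triage

A record carries either a reading or a device error code, never both.
Operator mistakes (under-filled strip, mis-inserted strip) are *user
errors*: the affected rows stay in the data with `user_error = TRUE` so the
drop decision is auditable, but they are invisible to every statistic and
tally. Everything the instrument itself reports — faulty-strip/cuvette
codes, and `lo` under-range displays, which are represented as error codes
rather than numeric values — counts as a *device error*. The per-model error
rate uses valid + errors as denominator, reported to one decimal; this
denominator choice is forced by the printed rates such a study reports
(e.g. 4 errors against 106 valid samples → 3.6%).

Units are standardized at analysis time: mmol/L readings are multiplied
by 18. The 1.11 whole-blood→plasma factor is shipped as a utility
(`plasma_equivalent()`) because it explains the hematocrit sensitivity
mechanism, but the pipeline never applies it — meters and reference both
already report plasma-equivalent values.

## Summary statistics

Per (device model, condition), pooled over days, units and lots:
mean percent bias (trueness), MARD (mean |deviation|), and the sample
(n−1) standard deviation of the signed deviations (precision; the
denominator is a package choice, immaterial at n = hundreds). The 95%
limits of agreement re-express (bias, SD) in mg/dL at the stratum's nominal
glucose $G$: $G\,(1 + (b \mp z\,s)/100)$ with $z = 1.96$ — the standard
two-sided normal 95% multiplier, configurable; the multiplicative form is
used because both bias and noise are relative quantities on this data.
Empty cells yield `NA`, never zero.

## Guideline bands

Mean bias per cell is banded green (|bias| ≤ 8%), orange (8% < |bias| ≤ 15%)
or red (> 15%). The thresholds are the UNICEF/NEST360 TPP minimal accuracy
target (±8%, also the proposed CLIA limit), the ISO 15197:2015 percentage
limb (±15%), and — for the point-fraction table only — the older 2003
ISO ±20%. Boundary values belong to the inner band ("within ±8%" includes
8). Percentage limits are applied at *all* glucose levels, including below
100 mg/dL, to keep devices comparable across strata; the ISO absolute-mg/dL
limb for low glucose is deliberately not implemented (the `thresholds`
argument is the extension point). Point-level compliance is summarized as
the fraction of deviations within each threshold, which is monotone in the
threshold by construction.

## Parkes error grid

Clinical consequence is graded on the Parkes (consensus) error grid for
Type 1 diabetes, the variant used for regulatory evaluation. The breakpoint
coordinates are the published consensus values; they ship both as code
defaults and as an overridable YAML file. Two representational choices
matter:

- **Nested cumulative polygons.** Zone polygons are stored as "this risk or
  better" regions, A ⊂ B ⊂ C ⊂ D ⊂ E = domain. A point's zone is the first
  polygon that contains it. This makes the partition property (exactly one
  label per point) true by construction, and resolves boundary points to
  the lower-risk zone deterministically — the conventional inclusive-toward-
  safety reading of the grid lines.
- **Hand-rolled inclusive point-in-polygon.** Classification uses a
  vectorized even-odd crossing test with explicit on-segment detection
  (tolerance 10⁻⁹ on perpendicular distance), because boundary inclusivity
  must be controlled. The test suite checks it against an independent
  point-in-polygon implementation (`mgcv::in.out`) on random continuous
  points, where boundaries have measure zero.

The domain is capped at 550 mg/dL (the grid's standard extent);
out-of-domain *points* are a domain error for `classify_points()`, while
condition-average meter values are clamped to the domain with a warning.
Averages are zoned from the pooled per-condition mean reference and mean
meter values (the way such grids display condition-level results; per-day
zoning is available by calling `classify_points()` on any table), with the
±1 SD meter interval emitted for plotting.

## Device grouping

The published groupings of such panels are narrative; `rank_devices()` is
an explicit, deterministic reconstruction, labeled as such in every report:
red anywhere or SD > 15% at low glucose → Group 4; any orange, or a failed
overall precision gate (max SD > 10%) → Group 3; otherwise cost splits
Group 1 (high consumable cost) from Group 2 (meets the cost target, or
unknown). All thresholds are arguments. The rule is monotone — improving
any bias or SD toward zero never worsens the group — and order-independent.
Cost tiers are configuration inputs, never computed. Alternative weightings
amount to different thresholds and are selectable through the arguments.

# The study simulator

`simulate_study()` emulates the bench design with known ground truth:

- **Panel**: per (day, condition), realized glucose and hematocrit are the
  targets plus Gaussian day-to-day jitter (defaults: SD 5 mg/dL and 2
  hematocrit points — the magnitude of day-to-day sample-preparation
  scatter one would accept on such a bench), truncated to physiologic
  bounds (glucose ≥ 10 mg/dL, hematocrit 5–70%).
- **Reference**: five replicates/day/condition by default, Gaussian with a
  1% relative SD — consistent with an analyzer held to a ±5% linearity
  specification.
- **Device model**: percent deviation from true glucose is Gaussian with
  mean `base_bias + hct_coeff · (hct − 40)` and SD interpolated linearly in
  glucose between anchors at 40 mg/dL (`sigma_low_pct`) and 150 mg/dL
  (`sigma_high_pct`). The noise is defined *on the percent-deviation
  scale*, so `sd_percent()` is an unbiased target of `sigma_*` — defining
  it multiplicatively on the biased expectation instead would shrink the
  recovered SD by the factor (1 + bias/100). The linear hematocrit term
  centered at a normal adult hematocrit of 40% is the simplest form
  consistent with the negative-bias-at-high-hematocrit behavior of real
  strips; the two-anchor relative noise reproduces the ubiquitous loss of
  precision at low glucose with the fewest parameters.
- **Failure modes**: each replicate becomes a device-error record with
  probability `error_rate`; readings below `display_floor` become `lo`
  error records; `reads_mmol` devices emit value/18 in mmol/L (exactly, so
  unit round-trips are lossless).

All draws come from one base-R generator: `simulate_study()` seeds once and
draws panel jitter, reference replicates, then per device (profiles in
order) a noise vector and an error vector; the stage functions seed with
fixed offsets of `design$seed` so each stage is independently reproducible.
`write_truth_manifest()`/`read_truth_manifest()` serialize every generative
parameter plus the seed; a manifest without a seed is refused.

What the simulator does **not** model: hemolysis, lipemia, temperature,
strip-lot drift, capillary-vs-venous differences, or the neonatal red-cell
properties (higher MCV/RDW, different metabolism) that distinguish true
neonatal blood from hematocrit-adjusted adult blood. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and well-calibrated on
its stated model, not that any real meter will behave like a profile. The
eleven shipped profiles are synthetic archetypes for demos and tests; they
are labeled as such and must not be read as measured characteristics of
real products.

# Numerical and testing choices

- Internal computation is in full double precision; reports round to one
  decimal at the formatting stage only.
- The statistics are checked against independent naive-loop oracles to
  10⁻⁹ on 1,000 random datasets, and the grid classifier against
  `mgcv::in.out` on 10,000 random points, plus an exhaustive 1-mg/dL
  lattice partition check (551² points).
- The end-to-end null test (all-zero profiles, zero reference noise)
  requires *exact* zeros through the whole pipeline — a strong guard
  against accidental recentring or unit slips.
- Parameter recovery runs a 16-profile grid (bias −15/−5/0/+5%, σ 3/10%,
  hematocrit coefficient 0/−0.2%/point) over 50 days × 5 replicates ×
  6 conditions (250 points per cell). At that size the Monte-Carlo
  standard error of a recovered cell bias is σ/√250 (0.63% at σ = 10%),
  so a fixed ±1% acceptance band on every one of the 96 cells sits at
  ~1.6 standard errors for the σ = 10% profiles and will be exceeded
  somewhere in most realizations; the suite nevertheless asserts the ±1%
  band as specified for this design, alongside a statistically calibrated
  3σ/√n check at n = 500 in the unit tests. SD recovery (±15% relative,
  ~3.3 standard errors) and error-rate recovery (3 binomial SDs) are
  well-calibrated at these sizes.
- Test problem sizes (six-day demo studies, 50-day recovery runs, the
  551² lattice) were chosen as the smallest sizes at which the checks are
  meaningful; the full suite runs in well under a minute.

# Known limitations

- The grid ships only the Parkes Type-1 consensus zones; Clarke,
  surveillance and neonatal-specific grids (none exist to date) are out of
  scope, though any nested-zone set can be supplied via
  `load_zone_polygons()`.
- Banding implements the percentage limbs only, not the ISO low-glucose
  absolute limb, and makes no claim of formal ISO 15197 system-accuracy
  certification (which prescribes a specific glucose distribution and
  95%-of-points criterion).
- No regression-based bias modeling (Deming, Passing–Bablok): the
  stratified design analyzed here estimates bias per condition directly.
- The device grouping is a reconstruction of a narrative rule; its
  thresholds are explicit arguments precisely because the original is not
  formulaic.
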