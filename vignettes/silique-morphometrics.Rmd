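---
title: "Silique morphometrics from instance masks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silique morphometrics from instance masks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siliquant)
```

## The measurement model

A silique (the elongated fruit of *Arabidopsis* and other Brassicaceae) is
approximated as a tube: a smooth centerline with a slowly varying circular
cross-section. From a single per-instance binary mask — the output of an
instance segmentation network or a hand annotation — four traits are
computed:

* **Area (SA, mm²)** — the count of foreground pixels, scaled by the pixel
  pitch squared. The pitch is `25.4 / dpi` mm; flatbed scans in the target
  workflow are 300 dpi, so one pixel is ≈ 0.0847 mm.
* **Length (SL, mm)** — the mask is thinned to a one-pixel spinal line,
  small side branches are pruned, and the ordered path is summed step by
  step (1 for orthogonal moves, √2 for diagonal moves).
* **Diameter (SD, mm)** — twice the largest Euclidean distance transform
  (EDT) value along the spinal line: the widest disk inscribed in the mask
  and centred on the skeleton.
* **Volume (SV, mm³)** — a stack of thin circular disks along the spinal
  line, each with radius equal to the local EDT value, summing
  `π r(s)² ds`. This assumes each cross-section is circular with radius
  equal to the half-width of the mask — reasonable for turgid, unshattered
  fruit, optimistic for flattened or twisted ones.

Per-instance masks are *amodal*: where two fruits overlap in a scan, the
shared pixels belong to both instances. A label image cannot represent
this, which is why all I/O keeps one raster per instance (COCO RLE or a
PNG-per-instance folder).

## Quality control before measurement

Network predictions occasionally merge touching fruits or fragment one
fruit into pieces. Two structural filters reject such masks before any
trait is trusted:

1. **Single component.** The mask must be one 8-connected region
   (`multi_component` otherwise; an empty raster is `empty_mask`).
   8-connectivity matters: thin diagonal organs disconnect under
   4-connectivity.
2. **Single clean spinal line.** After thinning, terminal branches of at
   most `max_spur_px = 5` pixels are pruned (shortest first, re-thinning
   after each deletion so the junction pixel is reabsorbed). Spurs are
   measured as the pixels from the branch tip up to, but excluding, the
   branch point. Anything longer than 5 px that still leaves a branch
   point is deemed significant — typically one mask covering two fruits —
   and the instance is rejected as `residual_spur`. A skeleton with no
   endpoints (a mask with a hole) or fewer than two pixels is
   `degenerate_skeleton`.

The 5 px threshold treats sub-threshold spurs as thinning artifacts and
super-threshold ones as structural: pruning small ones keeps harmless
wobbles from discarding good fruit, while rejecting persistent branches
avoids measuring a "length" that silently runs down the wrong limb.

### Which thinning operator?

The classic two-subiteration parallel thinning of Zhang & Suen (1984) has
a documented flaw: both pixels of a 2-px-wide diagonal pair satisfy its
deletion conditions in the same subiteration, so 45° limbs can be erased
entirely (we reproduce this on a 45° tube, which collapses to a single
pixel). `binary_thin()` therefore uses the connectivity-preserving
subcycle conditions of Guo & Hall (1989), in the form tabulated by Lam,
Lee & Suen (1992) — the same conditions mainstream image libraries apply
when asked for this family of thinning. The implementation was checked
two ways: the condition formulas regenerate scikit-image's thinning
lookup tables exactly, and tubes rasterised at angles 0–90° all thin to a
single two-endpoint line.

## Numerical behaviour of the estimators

The synthetic capsule generator makes these biases measurable, because a
capsule (all points within `r(t)` of a centerline) has closed-form truth:
arclength, max radius, area `∫2r ds` plus half-disk caps, and disk-stack
volume `∫π r² ds`. A pixel is foreground iff its centre lies within the
local radius, so the analytic truths are exact statements about the
rasterisation rule; sub-pixel placement of the centerline makes pixel
counts unbiased. On 200 seeded random capsules (length 60–180 px, radius
4–9 px, gentle curvature, constant or mid-bulged profiles):

* **SA** is within ±1.5% of truth (tested at 3%).
* **SD** is within +1.9/−0.2 px of `2 r_max` (tested at 2 px). The EDT
  measures distance to the nearest background pixel *centre* with no
  half-pixel correction, a deliberate match to common library semantics;
  it contributes a systematic ≈ +0.5 px to the radius.
* **SL** measures the *digital* (chain-code) length of the spinal line:
  summing 1/√2 steps over-measures a straight line by up to +8.2% at
  ≈ 22.5°, and thinning insets each tip by up to one local radius. The
  capsule truth therefore also records the expected chain-code length of
  the digitised centerline; SL recovers that quantity within ±2 r (in
  practice within ≈ ±6 px). No tip-inset correction is applied — the
  measure is reported as defined.
* **SV** combines both EDT radius bias and skeleton-path geometry. Disk
  heights default to the local step length (`height = "step"`, a
  trapezoidal `∫π r² ds`); the literal one-pixel-high reading
  (`height = "unit"`) is available but undercounts rotated pods by up to
  ≈ 29% at 45°, because a diagonal path covers √2 arclength per pixel.
  With the default, recovery on the 200-capsule suite stays within a
  frozen ±25% band of the cylinder integral (typically within ±16%).

Uniform dilation of a mask never decreases SA, SD or SV, and traits are
stable under 90° rotation (SA < 2%, SD < 1 px) — both are enforced as
property tests.

## Sample-level phenotypes and statistics

Per sample (one pot, possibly several plants, scanned as one or more
images), accepted instances are aggregated into mean, percentiles
(linear interpolation between order statistics — R's default type 7;
alternative conventions move P95 by less than one inter-fruit gap), and
the relative standard deviation (sd/mean, an n−1 standard deviation), a
scale-free uniformity measure. Samples with no accepted instance are
reported missing, never zero. Rejections are counted per sample so
rejection rates can be recomputed from the tables alone.

Exclusion bookkeeping operates at the genotype level: a flagged genotype
(e.g., plants with many aborting fruit, an upstream biological judgment
this package only honours) loses *all* replicate samples across batches
and treatments. The synthetic study manifest reproduces the arithmetic of
the emulated experiment — 2,801 samples over 485 genotypes, of which 123
flagged genotypes remove 702 samples, leaving 2,099 across 362 genotypes.

Two statistics support downstream genetics:

* **Paired treatment test.** Genotype is the pairing unit (it is the only
  unit present in both treatments): each genotype contributes its mean per
  treatment and a classical paired t-test runs on the differences.
  Under a null population (no treatment effect) the type-I error at
  α = 0.05 calibrates to 0.05 ± 0.02 over 1,000 simulated populations of
  60 lines × 3 replicates — a size chosen to keep the calibration fast
  while leaving the binomial standard error (≈ 0.007) well inside the
  band.
* **Broad-sense heritability.** One-way ANOVA method-of-moments
  repeatability per treatment: `H² = σ²_line / (σ²_line + σ²_resid)` with
  the standard unbalanced `n₀` correction, clipped to [0, 1]. Over true
  H² ∈ {0.1, …, 0.9} at 300 lines × 3 replicates, mean absolute recovery
  error is ≈ 0.02 (tested at < 0.1). The estimator ignores batch; if
  batch effects inflate residual variance this is a conservative
  (downward-biased) repeatability.

The phenotype generator draws
`value = μ + line_effect + effect·[group] + ε` with Normal line effects
and residuals. Its defaults emulate the target experiment's shape — 485
lines, two social treatments, three replicates, a trait scale like
silique length in mm (μ = 12, line sd 0.8, residual sd 1.0, treatment
shift 0.6, giving within-treatment H² ≈ 0.39). What it does *not*
emulate: batch effects, genotype×treatment interaction, non-Gaussian
tails, or any genetic map structure — so passing calibrations here show
the estimators are correct, not that real silique data meet their
assumptions.

## Detection and segmentation evaluation

`evaluate_detections()` reimplements the standard benchmark protocol:
greedy score-ordered one-to-one matching (ties broken by stable input
order, then lowest ground-truth index), AP from the 101-point
interpolated precision–recall sweep, AR as mean recall, both averaged
over IoU 0.5:0.05:0.95 and reported as percentages for boxes and masks
separately. The greedy matcher is verified against an exhaustive
assignment search on random small scenes; perturbation constructions
(identity, calibrated erosion) pin the expected AP values exactly. The
101-point convention is a documented choice — the metrics' namers do not
specify an interpolation — and an all-point variant is available
(`interpolation = "all"`). No per-image detection cap and no object-area
ranges are applied.

## Problem sizes and determinism

Every stochastic stage takes a single integer seed and restores the
caller's RNG state. Suite sizes — 200 capsules for trait recovery, 100
scenes for the matcher oracle, 1,000 populations for the type-I
calibration, 9 grid points × 300 lines for heritability — were chosen as
the smallest sets that make the tested tolerances meaningful, and run in
well under a minute each on one core. Workflow commands write a
provenance block (command, package version, seed, config) beside their
outputs, and reruns with the same config are byte-identical.

## Known limitations

* Trait definitions assume an unbranched, non-self-intersecting fruit;
  strongly curled pods whose mask self-overlaps will be rejected (or
  mis-measured if the overlap is tangential).
* SL is a digital length with orientation-dependent bias (≤ +8.2%) and an
  uncorrected tip inset (≤ one radius per end); comparisons across
  samples are fair, absolute lengths are slightly conservative at the
  tips and generous on diagonals.
* SV inherits the circular cross-section assumption and the EDT's
  half-pixel radius bias; it is a relative, not absolute, volume proxy.
* The mask-folder metadata schema is this package's own versioned
  reconstruction of a per-instance annotation layout; compressed RLE
  support is validated by round-trip, not against an external codec.
* The QTL scan itself (mixed models, kinship, thresholds) is out of
  scope; `export_qtl_tables()` produces the line × metric tables and
  covariates that external multiparent mapping software consumes.
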