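---
title: "Methods: quantifying relative thalamic atrophy from label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying relative thalamic atrophy from label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yrrta)
```

## The index and its rationale

Gray-matter atrophy — and thalamic atrophy in particular — tracks
disability and progression in multiple sclerosis better than white-matter
measures, but absolute regional volumes vary widely across people and
must normally be normalized by intracranial volume and adjusted for age.
The yearly rate of Relative Thalamic Atrophy (yrRTA) sidesteps both
problems by forming an *intra-patient* longitudinal ratio: the thalamic
shrinkage observed between two scans is compared with the concurrent
enlargement of the ventricular system, which serves as an internal
yardstick for unspecific, global brain atrophy. Each subject is their own
control; no external normalization is required.

Two measurement modes are supported:

* **2D (planimetric)** — areas traced on a single axial slice passing
  through the foramen of Monro / interthalamic adhesion: right and left
  thalamus ($A$, $A'$) and the whole ventricular system on that slice
  ($B$). This is deliberately low-tech: it can be done with the area tool
  of any DICOM viewer.
* **3D (volumetric)** — volumes of right/left thalamus ($A$, $A'$),
  right/left lateral ventricle ($C$, $C'$) and third ventricle ($D$),
  from any manual or automated segmentation.

With subscripts 1 and 2 for baseline and follow-up and $m$ the inter-scan
interval in months, the rates are

$$\mathrm{yrTA} = \big[(A_1 + A'_1) - (A_2 + A'_2)\big] \times 120 / m$$

$$\mathrm{yrVE}_{2D} = (B_2 - B_1) \times 120 / m,
\qquad
\mathrm{yrVE}_{3D} = \big[(C_2 + C'_2 + D_2) - (C_1 + C'_1 + D_1)\big]
\times 120 / m$$

$$\mathrm{yrRTA} = \Delta TA \times 120 \,/\, (\Delta VE \times m)$$

where $\Delta TA$ and $\Delta VE$ are the raw (un-annualized)
differences. Positive yrTA means the thalamus shrank; positive yrVE means
the ventricles enlarged.

### The two ratio conventions

The printed yrRTA formula is *not* the algebraic quotient of the two
rates: $\mathrm{yrTA}/\mathrm{yrVE} = \Delta TA / \Delta VE$, with the
annualization cancelled, whereas the printed form retains a
$120/m$ factor. Both are implemented — `convention = "as_printed"`
(default, faithful to the published formula) and
`convention = "pure_ratio"` (the dimension-free quotient) — and the
discrepancy is surfaced rather than silently resolved. They differ
exactly by the factor $120/m$, a relationship asserted in the test
suite. The constant 120 is not motivated by its source; it is kept as
the default and exposed as `factor` rather than reinterpreted.

When $\Delta VE = 0$ (a perfectly stable ventricular system) the yrRTA
is undefined. It is returned as a flagged `NA` — never an error — so
batch tables containing stable patients still compute, and undefined
values are excluded from group means with an explicit count
(`n_yrRTA_undefined`), never imputed.

## Qualitative classification

Normative cutoffs for yrTA and yrVE are still to be established by
validation studies, so the package (and its CLI) **refuses to classify
without explicit user-supplied cutoffs**. Given cutoffs, each rate is
categorized by strict inequality — `High` iff the value exceeds the
cutoff, so a value exactly at the cutoff is `Low` (a fixed, documented
tie-break) — and the pair is mapped through the complete truth table:

| yrTA | yrVE | derived yrRTA | risk of progression |
|------|------|---------------|---------------------|
| Low  | Low  | Normal        | Low  |
| Low  | High | Low           | Low  |
| High | Low  | High          | High |
| High | High | Normal        | High |

The derived yrRTA category comes from this table, not from thresholding
the numeric yrRTA: concordant rates give `Normal`, and only the
discordant combinations are informative on their own. The
(High, High) `Normal` row — generalized atrophy — is numerically similar
to the (Low, Low) row; distinguishing them is left to the clinical
context and to the reported yrTA/yrVE categories, which the package
always emits alongside.

## Measurement conventions

* **Orientation.** Every NIfTI volume is reoriented on load to a
  canonical RAS frame using its qform/sform, so the third array axis is
  always inferior→superior and "axial slice $k$" is unambiguous.
  Reorientation only permutes/flips axes and never changes per-label
  voxel counts (asserted by test). Slice indices are 1-based, matching
  R indexing; the CLI reports them as such.
* **Reference slice (2D).** The anatomical instruction — the slice
  through the foramen of Monro / interthalamic adhesion — is
  operationalized as: among axial slices containing *both* thalamus
  labels, the slice with maximal third-ventricle cross-section, ties
  broken toward the most inferior slice. The interthalamic adhesion
  crosses the third ventricle where the thalami flank it, so the
  maximizer is the mask-space analogue of the landmark. A
  `slice_override` argument (CLI `--slice`) preserves protocol fidelity
  when a human has picked the slice.
* **Areas and volumes.** Labels are binary per voxel; areas are pixel
  counts × in-plane pixel area, volumes are voxel counts × voxel
  volume. No partial-volume weighting — this matches planimetric
  tracing in a DICOM viewer. Consequently areas scale exactly as
  $k^2$ and volumes as $k^3$ under spacing scaling, and summed slice
  areas × slice thickness equal the volume (Cavalieri identity), all
  asserted as properties.
* **Region B.** The 2D ventricular area is the union of both
  lateral-ventricle labels and the third-ventricle label on the slice;
  posterior/occipital horns belong to the lateral-ventricle labels, so
  no separate horn label exists.
* **Interthalamic adhesion.** Thalamus tracings must exclude the massa
  intermedia; in mask space that is the segmenter's responsibility.
  The detectable violation — left and right thalamus labels 6-connected
  across a face — triggers a warning.
* **Months.** When derived from two dates, a month is days / 30.4375
  (mean Gregorian month); an explicit month count always wins.
* **Label maps.** Default labels 1–5; a built-in `"aseg"` preset
  matches the FreeSurfer convention (49/10/43/4/14) for automated
  pipelines, and any role can be overridden.

## The synthetic phantom

No clinical images accompany the method, so verification rests on a
synthetic five-structure phantom with exact, recountable ground truth:
two ellipsoidal thalami flank a midline third-ventricle slab, with two
arc-shaped (partial cylindrical shell) lateral ventricles lateral and
superior to them. The default geometry is a test fixture of realistic
magnitude (thalami ≈ 3.3 cm³ each, lateral ventricles ≈ 2.4 cm³ each,
third ventricle ≈ 0.8 cm³ at 2 mm spacing), not an atlas fit. The slab
has a parabolic axial width profile so the reference-slice rule has a
well-defined maximizer, and the arcs extend slightly below the
thalamic equator so the lateral ventricles are visible on the reference
slice, as they are at the foramen of Monro level.

Voxelization is by voxel-center inclusion. On the default ellipsoid
(semi-axes 10 × 8 × 6 mm) the measured volume is within 1.9 % of the
analytic $\tfrac{4}{3}\pi abc$ at 2 mm, 0.53 % at 1 mm and 0.019 % at
0.5 mm — monotone convergence that the acceptance suite asserts.

### Longitudinal change with exact targets

Follow-up anatomy is produced by morphological editing with exact
voxel-count targets, not affine rescaling, so ground truth stays exact:

* **Thalamic loss.** Voxels are ranked by interior depth (a 6-connected
  peeling distance); the deepest $\mathrm{round}((1-f)\,n_0)$ survive.
  This is erosion refined to an exact count: whole layers are removed
  until the target lies inside a layer, and that layer is trimmed
  deterministically.
* **Ventricular gain.** Background voxels are added in 6-connected
  dilation rings until $\mathrm{round}((1+g)\,n_0)$ is reached, growth
  restricted to background (label 0) so no structure ever claims
  another's voxels. Thalami are shrunk first, freeing background that
  the ventricles — the third ventricle in particular — may then claim,
  mirroring the anatomical coupling between thalamic atrophy and
  third-ventricle enlargement.
* **Partial layers** are trimmed in a deterministic low-discrepancy
  order (golden-ratio hash of the voxel index) rather than raw index
  order. Raw index order would concentrate all sub-layer change at one
  end of a structure; the spread order approximates the spatially
  uniform sub-voxel boundary displacement that real slow atrophy
  produces, which matters for single-slice (2D) measurements.

Because targets are hit exactly, applied loss fractions of 1 %, 3 % and
5 % are recovered through the full measurement pipeline to within one
voxel-equivalent (relative error ≈ $1/n_0$, about 0.015 % at 1 mm).

### Cohort simulation

`generate_cohort()` mimics a small proof-of-concept design: three groups
(healthy controls, CIS non-progressors, CIS progressors; default 5/5/5),
two scans 9–15 months apart. Per-subject *yearly* rates are drawn from
group-specific normals, truncated at zero, and scaled by the subject's
actual interval. Defaults: thalamic loss 0.5 %/yr (SD 0.3) in controls
and CIS−, 3 %/yr (SD 1) in CIS+; ventricular gain 1 %/yr (SD 0.5) in
controls and CIS−, 2 %/yr (SD 0.8) in CIS+. These magnitudes bracket the
published range from healthy aging to early, progressing MS, with the
progressor group showing the disproportionate deep-gray component the
index targets. Anatomical variability is a per-subject global size
factor (SD 3 %). All draws flow from one seed, so equal specs reproduce
bit-identical cohorts.

Both timepoints of every subject are measured with the same morphometry
code a user would run. The follow-up 2D measurement reuses the
baseline's reference slice: phantom anatomy does not move between
scans, so re-running slice selection would only inject landmark
re-identification noise, which the generator deliberately does not
model (see limitations).

With these defaults and $n = 20$/group, the mean 3D yrRTA of the
progressor group exceeded the control mean in 100 of 100 replicate
cohorts in the acceptance run — the qualitative ordering
(CIS+ > controls ≈ CIS−) expected of the index. Group means are
reported for defined yrRTA values only.

## Numerical and design choices

* **Formula grouping.** The printed formulas carry no grouping
  parentheses; each is read as [whole sum-difference] × 120 /
  denominator — the only reading consistent across all three columns.
* **Problem sizes.** The test and acceptance runs use the 2 mm default
  phantom for cohort work and 0.5–1 mm grids for accuracy and recovery
  checks; these sizes make every stage verifiable in seconds to minutes
  while keeping quantization effects visible rather than hidden.
* **Degenerate inputs.** Empty tables, empty cohorts, absent structures
  (0 mm³ plus a warning), all-background volumes and zero-change pairs
  all flow through with defined results; only genuinely contradictory
  inputs (overlapping phantom structures, unreachable growth targets,
  non-positive intervals) abort, with the offending entity named.
* **Determinism.** Phantom generation and change application contain no
  randomness at all; cohort generation consumes a single seeded stream.

## What the phantom does and does not show

The generator validates the *measurement and rate machinery*: exact
label bookkeeping, formula correctness, recovery of known change, group
ordering under a known generative model. It does not emulate MRI
intensities, scanner noise, motion, segmentation error, registration
error, or landmark re-identification variability between visits —
measurement noise enters only through rate-level sampling. Passing
tests therefore say nothing about tracing reproducibility on real
scans, about the validity of any particular cutoff, or about clinical
discrimination; published group means from real cohorts are expressly
illustrative and are not reproduction targets.

Known limitations of the method itself carry over: single-slice (2D)
scoring is quantization-limited — at 2 mm resolution a 1 %/yr
ventricular gain often changes the reference-slice area by zero pixels,
yielding undefined yrRTA for a substantial minority of simulated
stable subjects (reported, not hidden) — and conditions that alter
ventricular morphology independently of atrophy (e.g. hydrocephalus)
would distort the ratio's interpretation.
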