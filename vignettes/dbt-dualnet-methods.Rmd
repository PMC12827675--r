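---
title: "Pseudo-color enhancement and dual-branch classification of DBT lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dbtdualnet)
```

This vignette documents the model, the tunable parameters, the synthetic
phantom that stands in for clinical data, and the numerical and design
choices made where the method description left the design open. It states
no empirical numbers beyond those the test suite and
`scripts/acceptance.R` compute themselves.

## The classification problem

Digital breast tomosynthesis reconstructs a quasi-3D stack of thin slices
(here 1 mm apart, ~0.085 mm in-plane in the reference acquisition).
Radiologist annotations give, per lesion: the patient and view, the center
slice index, a 2-D bounding box on that slice, and a benign/malignant
label. The task is image-level benign/malignant classification from the
annotated region, with slice-level predictions as the intermediate.

## Pseudo-color enhancement

All colorspace arithmetic uses the 8-bit HSV convention with hue in
[0, 179], so the hue shift is integer arithmetic modulo 180:

* `adjust_hue`: H' = (H + ΔH) mod 180,
* `adjust_saturation`: S' = min(S·α, 255),
* `adjust_value`: V' = min(V·β, 255),

applied in that order (the order is immaterial — the three operations act
on disjoint channels — but it is pinned and tested). Defaults ΔH = 30,
α = 0.8, β = 15. Note that β = 15 drives every pixel with V ≥ 17 (i.e.
intensity ≥ 17/255) to the 255 ceiling; this is implemented literally and
is part of the transform's character, not corrected.

**Colorization before HSV.** A replicated grayscale image has S = 0 and
degenerate hue, so hue/saturation adjustments alone cannot produce visible
color. Two readings are implemented (`colorize_mode`):

* `intensity_to_hue` (default): H = round(intensity·179), S = 255,
  V = round(intensity·255). This produces a genuinely colored image whose
  hue encodes intensity, which is the only reading under which the hue
  shift has a visible effect.
* `replicate`: the literal reading; the pipeline then effectively reduces
  to value scaling.

Model-facing patches are floats in [0, 1]; colorspace operations run on an
8-bit view (×255, round half up). With identity parameters
(ΔH=0, α=1, β=1, replicate) the transform round-trips within one intensity
level, which the tests assert.

`histogram_equalize` is the standard CDF-based 8-bit equalization, the
conventional enhancement baseline (`pce.enabled = "histeq"`); constant
images pass through unchanged.

## Preprocessing geometry

Coordinates are 0-based `(x, y, width, height)` boxes with y downward and
half-open extents, matching the annotation CSV dialect. The steps:

1. **Orientation**: views whose tag starts with "r" are mirrored about the
   vertical axis (`x' = W − x − w` for boxes) so tissue is left-aligned;
   with no usable tag a mass-centroid heuristic decides and warns.
2. **ROI**: the box is expanded 10 px on each side (20 px per dimension),
   clipped to the slice, min-max normalized **per crop** (the description
   of intensity normalization is read as crop-local; per-volume would
   couple the patch contrast to unrelated anatomy), and resized to
   224×224 with bilinear interpolation (anti-aliased on downscale).
3. **Z-window**: 10 slices (10 mm at 1 mm spacing) around the center
   slice. The asymmetric split is −5/+4; at volume edges the window is
   shifted, not truncated, so it stays contiguous with 10 slices whenever
   the volume allows. Prediction uses the 2m+1 slices symmetric about the
   center within that window (default m = 1, the operating point at which
   the method reports its best image-level results).
4. **Augmentation** (training only, off by default in the desk profile):
   rotation by ±[10°, 30°] (sign uniform, zero fill in exposed corners)
   and integer shifts up to 10% of the side, deterministic per seed.
   Augmentation acts on the grayscale patch before enhancement so color
   statistics stay consistent.

## The dual-branch model

Each 3-channel patch passes through two backbone trunks (classification
heads removed). Branch outputs are adaptively pooled (deep branch to 1×1
always; shallow branch size configurable, default 1×1), flattened to
v_s ∈ R^{d_s}, v_d ∈ R^{d_d}, and linearly projected into a shared
d-dimensional space (default d = 256; the compact phantom profile uses
d = 32 to keep the projection head proportionate to the 32-dimensional
TinyCNN features). The registry pins the shallow/deep taxonomy
(ResNet50 is deep, per the published grouping, even though a
"≤50 layers" rule would also match it); TinyCNN may fill either slot.

Two classifier variants exist because the method's formula and its prose
disagree on what the head consumes:

* `concat_raw` (default): the head sees z = [v_d; v_s] and the projections
  feed **only** the similarity loss — the prose reading.
* `concat_projected`: the head sees [f̂_s; f̂_d] ∈ R^{2d} — the formula
  reading.

Both are implemented and tested; the default follows the more explicit
prose description.

**Loss.** Per slice, BCE on the sigmoid output (probabilities clamped at
1e−7 from the boundary) plus λ times the squared difference of the
projections. The reduction over the d dimensions is the **mean** (so λ's
scale does not depend on d; `sum` is available), and the gradient of the
similarity term flows into both branches (the literal reading; no
stop-gradient). λ defaults to 0.3, the best-AUC operating point, with
{0, 0.1, 0.3, 0.5} the conventional grid.

**Engine.** No deep-learning framework is available to R in this stack,
so the package ships its own small CPU engine: im2col/GEMM convolutions
(with stride, padding and groups — grouped and depthwise convolutions
cover ResNeXt and MobileNetV2), max/average/adaptive-average pooling,
batch normalization, ReLU/ReLU6, residual and densely connected composite
blocks, and Adam. Every layer's backward pass is verified against central
finite differences in the test suite; initialization is uniform with
fan-in scaling under a run-level seed. Training is single-threaded and
bit-deterministic given seeds.

## Voting and evaluation

Majority voting takes the mode of slice labels thresholded at 0.5
(boundary inclusive). With 2m+1 slices ties cannot occur; with even slice
counts they can, and resolve toward malignant — the sensitivity-favoring
choice consistent with screening practice; the policy is explicit and
configurable. Average voting thresholds the mean probability at 0.5
(inclusive). Image-level AUC always uses the mean slice probability.

Metrics come from the confusion table; undefined ratios surface as `NA`
with a warning rather than silently becoming 0. AUC is the rank-based
Mann–Whitney statistic with midrank ties (0.5 under total ties).
Cross-validation folds partition **patients**, stratified by class, never
slices. McNemar's test uses χ² = (b−c)²/(b+c) with the 1-df upper tail;
the continuity correction is off by default (matching the reference
arithmetic) and available as a flag.

## Grad-CAM fusion

Per branch, the "final convolutional layer" is taken to be the input of
that branch's adaptive pooling — well-defined for every registry backbone,
including densely connected ones where the choice of a named layer would
otherwise be ambiguous. Channel weights are the spatial means of the
logit gradient; the weighted sum is rectified, bilinearly upsampled to the
input resolution, and min-max normalized. Fusion sums the two
**un-normalized** weighted maps after upsampling to a common grid, then
rectifies and normalizes once — preserving the relative magnitude of the
branches' evidence (normalizing first would weight both branches equally
regardless of their contribution). A constant map normalizes to 0.5
(uninformative) rather than dividing by zero.

## The synthetic phantom

Each patient receives one volume with one lesion:

* **Background**: 0.3 baseline, a 10% laterality ramp toward the chest
  wall (making the orientation heuristic meaningful), and correlated
  Gaussian noise (sd 0.05) produced by an exact separable Gaussian blur
  (σ = 3 px) of white noise via banded-matrix multiplication.
* **Lesion**: an ellipsoid with in-plane radius
  r(θ) = r₀(1 + Σ_k a_k cos(kθ + φ_k)) and elliptic z-profile. Benign
  lesions use low-order harmonics (k = 2,3) at amplitude 0.05 — smooth,
  gently lobulated margins; malignant lesions use high-order harmonics
  (k = 5,7,9,11) at amplitude 0.35 — spiculated, angular margins. The
  malignancy signal is geometric, mirroring the radiological distinction,
  and deliberately not intensity-based: both classes share the same
  contrast (0.35 over background), so a classifier must read shape.
* **Annotations**: exact center slice and the tight bounding box of the
  geometric mask on that slice, written in the same CSV dialect the
  preprocessing reader consumes.

Defaults are desk-scale: 64 slices of 256×256 px at 0.5 mm in-plane / 1 mm
Z spacing, widths uniform in 5–80 mm (the clinical size range; the spacing
is a free parameter, so all millimeter-based logic is exercised, and
jointly rescaling spacing and sizes leaves pixel geometry bit-identical —
a tested invariant). Patients are generated from independent seed streams
derived from the cohort seed, so the pipeline streams them one at a time
(generate → extract patches → discard volume) with bounded memory while
remaining bit-identical to batch generation.

`separability_check` guards task solvability: the compactness statistic
perimeter²/area of the thresholded center-slice mask must separate the
classes (AUC well above chance at default texture). With equal margin
amplitudes for both classes the statistic carries no signal and the AUC
sits near 0.5 — both directions are tested.

**What the phantom does not emulate**: reconstruction artifacts and
out-of-plane blur, overlapping fibroglandular texture, calcification
clusters, multi-lesion cases, detector noise statistics. Passing the
phantom study shows the implementation learns a geometric margin signal
end to end; it says nothing about clinical performance on real DBT.

## Training profiles and problem sizes

The reference schedule is Adam at 3e-4 (the published operating point,
chosen there for long GPU schedules). The desk-scale phantom profile —
used by the acceptance script and the heavier tests — is: 100 patients,
m = 1 (300 slices), a 70/30 patient-level split, TinyCNN in both branches
(d = 32 projections), batch size 16, **10 epochs at Adam 1e-3**. The
higher rate is matched to the short schedule: at 3e-4 the 10-epoch budget
underfits, which is an optimization-budget artifact rather than a property
of the task. TinyCNN includes batch normalization for the same reason —
stable, fast convergence at small batch counts. Unit tests use smaller
cohorts (6–10 patients, 96–160 px volumes) chosen to keep the default
suite comfortably within a desktop run.

## Known limitations

* The engine is CPU-only and single-threaded; the large registry backbones
  are constructible and runnable (and their dimension bookkeeping is
  tested at reduced input sizes) but realistically trainable only with
  externally supplied weights and frozen trunks.
* DICOM ingestion is out of scope; volumes enter as arrays (the
  annotation dialect matches the public DBT collection, so an adapter
  only needs to stack the DICOM frames).
* The phantom's benign/malignant margin model is a two-class caricature;
  no "actionable" class, no detection (boxes are inputs).
* Histogram equalization operates on the 8-bit quantized view; images
  with fewer than ~256 distinct levels equalize coarsely.
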