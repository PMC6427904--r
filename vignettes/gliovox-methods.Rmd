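---
title: "Voxel-wise glioma segmentation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise glioma segmentation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliovox)
```

## The problem and the model

`gliovox` treats glioma segmentation as supervised per-voxel classification
on co-registered 4-modality MR volumes (Flair, T1, T1c, T2). Each voxel is
described by 62 features in four groups and classified into the five BraTS
tissue classes by a random forest; results are reported on three composite
regions (complete tumor, tumor core, enhancing tumor) with Dice, PPV,
sensitivity and specificity. The central assumptions are:

* modalities are co-registered on one voxel grid (no registration is
  performed here), and intensities are only meaningful after per-volume
  min-max normalization, because MR intensity has no tissue-specific scale;
* tumor compartments differ from healthy tissue both in local gradient
  structure (captured by 2D/3D gradient-magnitude statistics) and in the
  intensity profile of their surroundings (captured by in-plane ray
  features on T1 and Flair);
* class imbalance (tumor ≪ brain) is handled by training only inside the
  detected tumor bounding box on class-balanced samples, while evaluation
  uses every ROI voxel.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `sigma` | 0.5 | voxels | The smoothing scale is not prescribed by the method description; 0.5 denoises without erasing the thin enhancing rim. Configurable in `gx_config()`. |
| normalization statistics | whole volume | — | Matches the literal min-max formula including background zeros; `brain_only = TRUE` switches to nonzero-intensity statistics. |
| gradient boundary rule | one-sided | — | Central differences are undefined at volume faces; one-sided differences keep feature maps defined volume-wide (`boundary = "zero"` available). |
| cube sizes | 3, 5, 7 | voxels | Fixed by the feature-bank definition. |
| ray geometry | β=0, N_β=8, radii 10–20 step 2 | voxels/radians | The printed geometry ("8 rays … 45 circles ranging from 10 to 20 with even numbers") is internally inconsistent: even radii in 10–20 give 6 circles, not 45. The only reading compatible with the printed CCS feature count of 12 (2 modalities × 6 radius bands) is 6 circles; general ladders remain configurable via `ray_config()`. |
| H_min/H_max | 1st/99th percentile of brain voxels | intensity | The bound semantics are ambiguous in the source description; robust percentiles give bounded, contrast-invariant ray features. Percentiles configurable. |
| original CS angles | 0, π/2, π, 2π/3 | radians | Kept verbatim (the asymmetric 2π/3 is in the stated angle set); configurable if a symmetric 3π/2 is preferred. |
| mRMR discretization | μ±σ, 3 levels | — | The classic mRMR convention; makes plug-in mutual information estimator-free. |
| forest | 100 trees, mtry = ⌊√p⌋, grown to purity | — | Tree count is prescribed; other hyperparameters follow random-forest defaults and are documented in `train_forest()`. |
| f ladder | 62 − 5n, n = 0..12 | features | Prescribed sweep. |

## Ray features: sampling and reduction

Rays live in the axial plane only (slice thickness varies most along z).
A ray of angle θ and radius r is sampled at unit steps t = 1..⌊r⌋ at the
nearest voxel of (x + t·cosθ, y + t·sinθ); out-of-bounds samples are
dropped and a fully out-of-bounds ray contributes the background value 0.
The per-ray mean is normalized as (m − H_min)/(H_max − H_min) and clipped
to [0, 1]. Rounding uses ⌊v + 0.5⌋ in both the compiled and the reference
path so that results are bit-identical and exactly invariant under 90°
in-plane rotations when the angle set lies on the π/2 grid.

The reduction from (directions × radii) per-ray values to 12 CCS features
is not stated in the method description; we average the per-ray means
within each (modality, radius band) cell, with 6 equal-width bands over
[r_min, r_max]. This preserves the scale (radius) information while
matching the printed feature count. Note that ray means are cumulative
from the voxel outward, so a bright structure at radius ρ raises every
band whose radius exceeds ρ; the bands localize the *onset* of a
structure, not an annulus.

## mRMR and the dimension sweep

The set-level objective Φ = D − R (relevance minus redundancy) is
optimized by the standard greedy first-order increment: step 1 picks
argmax I(x; c); step k+1 adds argmax of I(x; c) − (1/|S|) Σ_{s∈S} I(x; s).
Exhaustive subset search is infeasible at 62 features; the greedy argmax is
verified against an independent exhaustive per-step oracle for ≤ 6
features in the tests. Ties break by registry order, making rankings
deterministic.

The sweep trains on the top-f features of one global ranking (computed on
the pooled balanced training sample) for each f, runs subject-level k-fold
cross-validation, ranks every available metric cell across f (higher is
better, mean rank on ties), sums ranks per f, and resolves rank-sum ties
toward the smaller feature set. All four metrics enter the ranking by
default; the caption of the source figure mentions three metrics and a
cell count that neither reading reconstructs exactly, so the metric subset
is a `metrics` argument. Undefined (NA) cells — e.g. LGG enhancing — are
dropped column-wise before ranking.

## The phantom generator: what it does and does not emulate

`generate_phantom()` builds nested ellipsoids: brain (class 0 background
tissue), edema shell (2), non-enhancing core shell (3), enhancing rim (4),
necrotic center (1); LGG-like phantoms merge the rim into class 3. Voxel
intensities are class/modality means plus Gaussian noise (sd 0.05), clipped
to [0, 1]; air outside the brain is exactly 0. The default mean table
encodes the radiological contrasts the features rely on — edema brightest
in Flair, enhancing core brightest in T1c, necrosis dark in T1/T1c — with
overlapping class distributions so that no single threshold separates the
classes. Cohorts jitter centers and radii by ±10% per subject.

The generator does **not** emulate bias fields, partial-volume effects,
anisotropic voxels, non-ellipsoidal lesion geometry, or inter-scanner
intensity variation. A green end-to-end test therefore establishes that
the pipeline's mechanics (features → selection → balanced training →
CV → region metrics) recover a stated, separable world; it does not
certify accuracy on clinical BraTS data, whose headline scores require the
actual dataset.

## Numerical choices and degenerate inputs

* Constant volumes cannot be min-max normalized and constant histograms
  have no bounds; both raise explicit degenerate-input errors. A
  consequence: predicting on an all-constant stack errors in preprocessing
  rather than returning an arbitrary uniform class.
* Population variance (divide by n) is used for all neighborhood and
  pooled variances, symmetric with the mean; tiny negative values from the
  E[x²] − E[x]² form are clamped to 0.
* Cube statistics and smoothing use edge-repeating reflect padding.
* Forest probability ties in argmax resolve toward the lower class label;
  mRMR score ties resolve by registry order; CV fold assignment is a
  deterministic shuffle under the master seed. All randomness (phantoms,
  sampling, bootstrap, folds) is seeded, so an entire sweep is
  reproducible bit-for-bit.
* Metrics with zero denominators are NA ("undefined"), never 0, and NA
  cells are excluded from cross-subject means and rank sums.

## Known limitations

* The random forest is a compact in-package CART implementation (no
  out-of-bag estimates, no variable importance); it exists because the
  execution environment provides no forest library, and it is validated on
  separable fixtures and the end-to-end recovery test.
* NIfTI support covers the common scalar datatypes of NIfTI-1 with
  orientation metadata ignored (volumes are assumed co-registered);
  MetaImage support is limited to uncompressed local-data `.mha`.
* Whole-brain (atlas-normalized) context features and 3D rays are out of
  scope; rays are axial-plane only.
* Specificity is computed inside the ROI cuboid by default, which is a
  stricter domain than whole-brain specificity; `domain = NULL` in
  `evaluate_segmentation()` evaluates the full volume instead.
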