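---
title: "Methods: multi-stage recognition of APL from bone marrow smears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage recognition of APL from bone marrow smears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the modelling strategy

Acute promyelocytic leukemia (APL) can be suspected from marrow
cytomorphology alone: the marrow is dominated by abnormal, heavily
granulated promyelocytes, a fraction of which carry needle-shaped Auer
rods, whereas other AML subtypes show a myeloblast excess and healthy
donor marrow shows few blasts of either kind. `aplsmear` operationalizes
exactly this reading process as a hierarchy:

* detect the nucleated cells,
* classify every cell for three binary attributes
  (myeloblast / promyelocyte / Auer rod),
* summarize a smear by the three call *ratios*,
* map the ratio vector to a diagnosis with a minimal linear model.

The hierarchical design is deliberate. A direct image-to-diagnosis
classifier needs far more labelled smears than a rare disease provides;
per-cell labels are plentiful by comparison, and the final image-level
model then only has to separate low-dimensional, strongly informative
ratio features. The final stage is intentionally the *smallest possible*
model — a single fully connected layer (affine map + sigmoid, no
dropout), so its parameter count is the number of features plus one and
its weights are directly interpretable.

Key assumptions baked into the pipeline:

* cells are approximately elliptical and mostly non-overlapping, so
  axis-aligned boxes with post-hoc ellipse refinement are an adequate
  region geometry;
* the three cell-level attributes are conditionally independent enough to
  be scored by separate binary classifiers (each cell carries a
  multi-label triple, e.g. a promyelocyte with one Auer rod is
  `(0, 1, 1)`; no mutual exclusion is imposed at prediction time);
* composition ratios are (near-)sufficient statistics of a smear for the
  two binary tasks — the diagnosis does not depend on where in the image
  the cells sit, which the permutation invariance of the ratio features
  makes structural.

# Stage models

## Detection

The detector is two-stage. Stage one is generative: a background colour
model (per-channel median of image border frames, pooled over training
images) defines a foreground mask at a deviation threshold
(`prop_threshold`, default 0.08 on the [0, 1] pixel scale); a
distance-transform watershed (tolerance 3 px) splits touching components;
components above `min_area` (60 px²) become proposals with moment-fitted
ellipses (for a filled ellipse the covariance eigenvalues are exactly
(a/2)², (b/2)², so the moment fit is unbiased). Stage two is
discriminative: a logistic scorer over nine region features (log area,
box fill, log aspect, mean RGB, luminance SD, mean background deviation,
axis ratio) trained full-batch with Adam, labelling training proposals
positive when they overlap an annotated cell at IoU ≥ 0.5. Smudge
artifacts enter training as negatives, which is how the detector learns
to separate viable cells from smudge.

Detections are confidence-thresholded (default 0.5), greedily
non-maximum-suppressed at IoU 0.5 (ties broken by lower region id, so the
procedure is deterministic and idempotent), clipped to the image, and
sorted by confidence. The human-in-the-loop round mimics annotator
correction: proposals overlapping ground truth at `iou_accept` are kept,
everything else is replaced by the reference region, and the detector is
retrained on the corrected set; with an untrained model the corrected set
is exactly the ground truth, and with `iou_accept = 0` all proposals are
kept verbatim.

Matching, NMS and mAP are computed on axis-aligned boxes — the standard
convention of detection benchmarks, which keeps the numbers comparable —
while ellipses remain a refinement product for display, cropping and
morphometrics.

## Per-cell classification

Each region is cropped via its box, padded to a square with the image
background colour (border cells are padded, never read out of bounds) and
resized aspect-preserving; the desk-scale default is 64 × 64 px while the
native-acquisition contract is 299 × 299 px (`detector_config()$crop_size`).

There is no deep-learning runtime in the package's dependency set, and at
desk scale none is needed: the classifier backbone is a *fixed* feature
extraction — 8 × 8 grid colour pooling per channel, 4 × 4 local-variance
pooling, channel and colour-opponency quantiles including extrema (the
crimson Auer rods live in the upper tail of R−B), 3 × 3 high-pass texture
energy (granulation), dark-pixel fractions (nucleus load) and foreground
fraction — topped by a trainable fully connected head of 1–3 layers with
ReLU, dropout and a sigmoid output, trained full-batch with Adam on
binary cross-entropy. Class imbalance (Auer-rod cells are rare) is
handled by augmented upsampling of the minority class to the majority
count: flips, right-angle rotations, per-channel colour shift and
brightness — exactly the operators that keep box/ellipse ground truth
valid — with each copy recording its parent and parameter draw. Augmented
copies inherit the parent's patient, so they can never cross a fold
boundary.

The tuned pooling-dropout values 0.32 and 0.46 are carried as the
defaults for the heads feeding the APL-vs-healthy and APL-vs-AML tasks
respectively; which task owned which value is not documented in the
source material, so the assignment here is a convention, and both are
plain configuration (`head_config(dropout = ...)`).

Morphometrics use the foreground mask: size is the pixel count, the
volume proxy is the sphere-equivalent volume of a disc of that area,
V = 4/(3√π)·A^{3/2} (so doubling both semi-axes multiplies it by 8), and
contrast is the RMS deviation of foreground luminance. They are attached
to every per-cell prediction; whether they also feed the ensemble net is
a configuration flag, off by default, because the ratio features are the
canonical inputs.

## Ensemble classification

`smear_features()` turns ≥ 1 per-cell predictions into
`ratio_X = #(p_X ≥ τ)/n` with τ = 0.5 by default; a zero-cell image
raises an explicit "unanalyzable" condition rather than fabricating a
call. `train_enn()` fits the single-layer model with Adam; a seeded
random-search over learning rate and epoch budget (five trials by
default, internal 2:1 patient split) stands in for heavier
hyperparameter optimization — reproducible from a plain seed and entirely
adequate for a 4-parameter model, with the search strategy pluggable
through `hpo()` (which also offers exhaustive enumeration for finite
grids).

# Evaluation protocol

* **Detection**: greedy confidence-descending matching, one ground truth
  per detection; AP is the area under the all-point-interpolated
  precision-recall curve of the pooled ranked detections; AR is maximal
  recall. Both are averaged over the IoU sweep 0.50:0.95 in steps of 0.05
  (ten thresholds — the sweep endpoints are the stated convention, the
  step is the benchmark default).
* **Classification**: AUROC via the rank statistic (ties worth ½, the
  probabilistic definition, which the tests pin to an exhaustive pairwise
  oracle); AUPRC as the rectangular step-curve area over all score
  thresholds (all-tied scores therefore give the prevalence, a useful
  sanity value); precision/recall/F1 at a 0.5 threshold.
* **Cross-validation**: folds are assigned to *patients*, stratified by
  diagnosis; with k = 3 every fold trains on 2/3 and tests on 1/3 of each
  class — the 2:1 split that prevents any patient from appearing on both
  sides. Macro averages are fold means with the SD of the fold values.
  Confidence intervals are deliberately not produced: the fold SD is the
  only dispersion reported.

The pipeline runs the whole protocol per fold (detector, three cell
heads and ENN are all retrained on the training patients only), so no
stage ever sees test-fold pixels or labels; the orchestration-level test
audits that every image is scored exactly once, in its patient's fold.

# The synthetic generator

The generator is the package's study population. It emulates, by
construction with exact ground truth:

* class-conditional composition — APL's promyelocyte family centred at
  0.63 (of which Auer-rod-bearing cells are a sub-fraction), AML's
  myeloblast fraction centred at 0.635, healthy marrow ≤ 0.05 blasts;
  these centres are the two cohorts' median marrow blast shares. A
  Dirichlet concentration of 8 gives a patient-level fraction SD of
  ≈ 0.16, matching the clinical interquartile spread; each patient draws
  one composition shared across their images, creating the patient-level
  correlation that grouped CV must respect.
* type-specific morphology — semi-axes 10–24 px at the 512 × 384 desk
  canvas, eccentric nuclei occupying a type-specific area fraction,
  granule densities far higher for promyelocytes than myeloblasts, 1–3
  Auer-rod line primitives confined to the promyelocyte family;
* nuisance structure — pixel noise, annotation-free smudge blobs the
  detector must reject, optional cell overlap (5% by default), and
  border cells clipped by at most ~30% of their area (placement margins
  of 0.42 of the box half-extents guarantee ≥ 70% visibility; their
  ground-truth boxes are clipped to the canvas, i.e. to what an
  annotator would draw).

What it does **not** emulate: true Romanowsky stain chromatics and
illumination gradients, dry taps and peripheral-blood contamination,
dense cell clumps, nuclear lobation, or faggot cells (rod *bundles*).
Consequently a green test suite here demonstrates that the pipeline's
machinery is correct and that it recovers the generator's parameters —
clean-synthetic metrics are upper bounds, not clinical performance
claims; the per-cell feature extraction in particular would need a
learned convolutional backbone for real stains (the head/config plumbing
already accommodates one).

# Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; stage seeds are
  derived from the master seed with a fixed LCG-style mixer kept below
  2³¹. Training is full-batch and single-threaded, so fixed seeds
  reproduce losses and predictions bitwise.
* Coordinates are 0-based with half-open boxes, origin top-left, pixel
  centres at half-integers; ellipse rotation is radians,
  counter-clockwise. One convention everywhere, converted only at IO
  boundaries.
* Zero-area boxes score IoU 0 (with a message); zero ground truth makes
  detection metrics an explicit error rather than silently 0; one-class
  inputs to AUROC/AUPRC, empty training sets, and zero-cell images all
  raise classed conditions.
* Ties: NMS and matching break confidence ties by lower region id; AUROC
  handles score ties by midranks.
* If a training fold lacks one class for a cell task entirely (e.g. no
  Auer-rod cell among a healthy fold's crops), the pipeline substitutes a
  constant-rate scorer for that task rather than aborting the fold.
* Malformed annotation regions are skipped and counted with a single
  summary warning; unknown region attributes round-trip untouched.

# Problem sizes

Desk scale is the default and the scale at which the packaged checks run:
512 × 384 px smears with ~25 cells (the native acquisition geometry,
2560 × 1920 px and 299 px crops, remains available through
configuration), 60-image detection splits (40 train / 20 test), 17
patients per cohort arm with two images each for the cross-validated
tasks, and 400/200-crop splits for the cell classifiers. These sizes keep
a full reproduction run in the ten-minute range on a single CPU while
leaving every statistical contract intact.

# Known limitations

* Clean synthetic smears are nearly separable at every stage; the
  pipeline's discriminative margins say little about stained marrow.
* Heavily overlapped cell clusters are out of scope: the watershed split
  handles touching pairs, not clumps.
* The detector's region scorer sees summary features, not pixels; highly
  textured artifacts that mimic cell statistics would defeat it.
* Only the two binary tasks are modelled; no three-class model, and no
  integration of clinical, genetic or laboratory covariates.
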