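---
title: "Methods: 3D fruit phenotyping from micro-CT with fruitct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D fruit phenotyping from micro-CT with fruitct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A micro-CT scan of a whole fruit yields a stack of grayscale tomograms —
one cross-section per depth step — from which a breeder wants
morphological traits without cutting the fruit open: outer size and
shape, but also internal quantities such as pulp (sarcocarp) volume,
rind (pericarp) volume and rind thickness that destructive calipering
measures poorly. For passion fruit the relevant tissue anatomy is a
pericarp shell enclosing a gas-filled gap and a pulp core of one to
three lobes. `fruitct` implements the full chain: weak-label generation
by classical image processing, semantic segmentation by a small U-Net
trained on those labels, 3D reconstruction, extraction of fourteen
traits, and cohort-level statistics.

Because no public CT dataset accompanies this problem, every stage is
validated on *synthetic phantoms*: parametric ellipsoidal fruit whose
fourteen traits have closed-form (or high-precision numeric) ground
truth. The phantom generator is first-class, tested code, not a test
fixture.

## The phantom model and what it does and does not emulate

A phantom (`phantom_spec()`) is an outer ellipsoid with semi-axes
$(a, b, c)$ (the long axis lying in the slice plane, as in a scan where
the fruit's longitudinal axis is parallel to the rotation platform), a
pericarp shell of per-axis thickness $t$, an air gap $g$ between the
shell's inner wall and the core, and 1–3 ellipsoidal sarcocarp lobes.
Lobes are parameterised in the normalised coordinates of the
gap-shrunken inner wall, where each lobe is a ball of radius $q$ at
offset $\delta$; containment ($\delta + q < 1$) and pairwise
disjointness ($\lVert c_i - c_j \rVert \ge q_i + q_j$) are then exact
inequalities, so every random draw is feasible by construction and the
sarcocarp volume is a closed-form sum.

The default `phantom_ranges("fruit")` profile reproduces the size
statistics of real cohorts: width 51–68 mm, length–width ratio
1.00–1.31 with length capped at 73.2 mm, pericarp thickness 1.5–5.5 mm.
A miniature `"desk"` profile (width 8–10.4 mm, so a fruit fits a
128 × 128 slice at 0.1 mm pitch) drives fast segmentation experiments;
it is a scaled geometry, not a different model. Voxelization assigns
each voxel the class of the analytic region containing its *centre*;
partial-volume effects are deliberately not modelled and are what the
measurement tolerances absorb.

Rendering (`render_ct()`) reproduces the three grayscale strata of real
tomograms: an exact-zero background stratum, uniform low-gray system
noise on (0, 60], and tissue drawn from one truncated normal
(mean 150, sd 30) on (60, 255] for pericarp and sarcocarp alike — the
two tissues are not separable by intensity, which is why segmentation
must be geometric. The default background zero fraction (0.379) makes a
frame that is about three-quarters background show roughly 29% zero,
47% low-gray and 24% tissue pixels. The phantom does **not** emulate
beam hardening, cone-beam artifacts, intensity gradients within tissue,
or non-convex fruit outlines; passing tests therefore demonstrate
correctness of the measurement chain, not robustness to every
acquisition pathology of real scanners.

## Weak labels from classical image processing

Per tomogram: a contrast transform zeroes values at or below the noise
ceiling `low_cut` (default 60) and stretches the rest; Otsu's threshold
is computed on the histogram of *strictly positive* raw pixels so the
abundant zero background cannot bias the split; contours of the binary
tissue mask are extracted with their full hole hierarchy and ranked by
enclosed (filled) area, keeping five. The largest contour is the fruit
outline, the second the pericarp inner wall, the third the sarcocarp;
the fourth (and, after it, the fifth) is merged into the sarcocarp when
its area strictly exceeds 25% of the third's — the strictness of the
gate is asserted by test. Pericarp is the region between contours one
and two.

One subtlety is where Otsu is applied. After a hard cut at the noise
ceiling the non-zero histogram is unimodal tissue, and an Otsu split of
it would land *inside* the tissue; the threshold is therefore computed
on the raw positive histogram and bounded above by `low_cut`
(`mask = raw > min(thr, low_cut)`), which behaves identically on noisy
and noiseless stacks. On nearly empty tomograms (beyond the fruit
poles) Otsu degenerates and labels dissolve into speckle; such slices
are caught by the quality filter and contribute background when slices
are stacked into a volume.

The quality filter automates the manual "pick the slices that look
right" step: it flags broken contour nesting, foreground touching the
image border, more than three sarcocarp components, a pericarp whose
shape matches no plausible section, and — on sections that contain
sarcocarp — a pericarp area fraction outside [2%, 60%] of the filled
fruit area. Two kinds of sarcocarp-free sections are deliberately
*eligible*: a clean ring (one connected pericarp component with exactly
one hole) and a compact solid cap (no hole, convex-outline circularity
≥ 0.8), because both occur in every real stack near the fruit poles.
Excluding them from training teaches the network to hallucinate pulp
where there is none — we measured held-out mean Dice of 0.81 (ring and
cap sections excluded) and 0.89 (caps still excluded) against 0.99 on
the tri-class validation split, with the deficit concentrated entirely
on polar sections. With both admitted, most in-fruit slices pass the
filter, and every unflagged slice agrees with voxelized truth at mean
Dice ≥ 0.95 (tested).

## The segmentation network

The network is a compact U-Net: per encoder level one 3 × 3
convolution + ReLU and a 2 × 2 max-pool, a bottleneck that doubles the
filters, and per decoder level nearest-neighbour upsampling,
concatenation of the encoder feature map, and one convolution; a 1 × 1
convolution emits three class logits. Defaults are depth 2 and 16 base
filters (57,955 parameters). Optimisation defaults:
batch size 4, RMSprop (alpha 0.99) with initial learning rate 0.001,
inputs scaled by 0.5 (2 × 2 mean pooling; labels follow by nearest
neighbour). The loss is plain multiclass cross-entropy, the standard default for
this kind of segmentation; nothing in the validation required class
weighting or a Dice-based loss. No
augmentation is applied. Training holds out one-sixth of the pairs for
validation and returns the checkpoint with the best validation mean
Dice; with a fixed seed the whole trajectory is reproducible. The
implementation is plain R over BLAS matrix products (im2col), which at
the desk scale trains in minutes on one CPU core.

Scoring uses per-class Dice and IoU with the empty-class convention
Dice = IoU = 1 when the class is absent from both volumes, so
all-background or sarcocarp-free slices do not zero out aggregates; the
identity Dice = 2·IoU/(1 + IoU) is asserted per class. `mDice_All`
averages the three classes; the `_Passion` aggregates drop background.

## The fourteen traits

Working on the tri-class label volume (rows × cols × depth, 0.1 mm
isotropic voxels by default):

* **FV** (fruit volume) is the *filled envelope*: tissue plus internal
  cavities and the shell gap, obtained by slice-wise hole filling. The
  content percentages make this unambiguous — typical cohort means for this fruit
  have SC + PC ≈ 52%, impossible if FV were tissue only. **SV**, **PV**
  count sarcocarp and pericarp voxels after component cleanup (largest
  envelope component; at most three sarcocarp lobes).
* **FSA** is isosurface area: the binary envelope is Gaussian-smoothed
  (σ = 1 voxel) and meshed by marching tetrahedra at level 0.5; a
  gradient-magnitude (coarea) integral of the same smoothed field is the
  config-selectable alternative. Both land within 1% of the analytic
  sphere; naive exposed-face counting overestimates it by ≈ 1.5× and is
  kept only as a negative control. On a cube the smoothing rounds the
  corners, a documented bias within 10%.
* **FW/FL** come from rotated-rectangle fits on the k = 5 mid-depth
  slices (the window around the slice of maximal envelope
  cross-section): the rectangle is oriented along the maximum caliper
  (Feret) diameter, the short side is the minimum caliper width, and the
  trait is the maximum over the window. The caliper orientation was
  chosen over the minimum-area criterion because the latter's angle is
  unstable on near-circular hulls (it cost 2–3% on rotated phantoms);
  on ellipses the two coincide. A side of n pixels measures
  (extent + 1) × pitch.
* **FMCA/FLP**: filled pixel count and convex-outline perimeter of the
  maximal mid slice (polygonal length, limiting pixel-edge quantisation
  bias; the fruit outline is convex for the phantom family).
* **PAT**: on each mid slice, up to 200 uniform random points on the
  pericarp inner boundary are paired with the nearest outer-boundary
  pixel; the grand mean distance plus one pixel (boundary centres sit
  half a pixel inside each wall — without the correction the estimate is
  biased low by a full pixel, about 10% at desk scale) times the pitch.
  Point-to-nearest-boundary is used rather than normal-ray casting for
  robustness to boundary noise. Deterministic per seed.
* **FLWR** = FL/FW; **FSI** = π^(1/3)(6·FV)^(2/3) / (FSA·FLWR)
  (sphericity divided by the aspect ratio, 1 for a sphere);
  **SC** = 100·SV/FV; **PC** = 100·PV/FV; **SFR** = 100·SV/(FV − PV),
  the pulp share of everything inside the fruit except the rind.

Ground truth for a phantom is analytic: closed-form ellipsoid volumes,
numerically integrated ellipsoid surface (400² spherical grid), ellipse
perimeter and mean shell thickness via dense point-to-ellipse distances.
A voxel-counting oracle at finer pitch exists (`method = "voxel"`) and
is used for grid-convergence checks at desk scale; at fruit scale a
quarter-pitch oracle grid (~3000³ voxels) would be pointless when the
closed forms are exact.

On a 20-phantom desk-scale cohort taken through the full classical
chain (voxelize, render with noise, weak-label every slice, stack,
measure), each trait's mean absolute percentage error against the
analytic truth stays within its budget: 2% for lengths, volumes, areas
and ratios, 3% for FSA and FSI, 5% for PAT (tested in the suite).

## Problem sizes and the streaming fruit-scale path

Desk-scale validation uses 128² slices. For full-size fruit at 0.1 mm
pitch a materialised volume is ~700³ voxels; since width/length (and the
other mid-depth traits) only need the k-slice window,
`measure_sample_classical()` streams: the per-slice envelope area
profile is evaluated from the phantom's quadratic form to locate the
window, and only window slices are rendered and weak-labeled. Rendering
the other ~700 slices would not change the result — the tissue mask
reproduces the label exactly when the threshold sits at the noise
ceiling — so this is a lossless shortcut, and one cohort sample takes a
few seconds instead of minutes. The width/length benchmark runs 20 such
fruit (seed 7 fixture); the segmentation benchmark trains on 240
desk-scale slices (seed 42 fixture, 20 epochs).

## Cohort statistics

Traits mix mm, mm², mm³ and percentages, so PCA standardises columns
first (correlation-matrix PCA); explained-variance ratios equal the
correlation matrix's eigenvalues over 14 (asserted against `eigen()`),
and each component's sign is fixed so its largest-magnitude loading is
positive. Pearson correlations carry two-sided t-test p-values
(n − 2 df) with significance marks at 0.05 and 0.01 and no
multiple-testing correction, matching common practice in phenotyping
reports. The composite quality score weights the first `n_dims = 3`
component scores by their explained-variance ratios normalised within
the retained set — the conventional reading of "weights from the PCA" —
and both the number of dimensions and the weighting are config-exposed
since other conventions exist. Min–max normalisation within a chosen
sample subset supports displaying trait contributions of top-ranked
samples on a common scale.

## Numerical conventions and degenerate inputs

* 26-connectivity in 3D (8 in 2D) everywhere components are counted.
* Contour ties on equal area break by hierarchy level, then topmost
  point; Otsu ties take the lowest level; mid-window ties take the first
  argmax slice.
* Empty contour sets, all-zero stacks, solid fruit without a cavity,
  zero-variance trait columns and missing classes all produce explicit
  errors, warnings or flags rather than silent results.
* All randomness (phantom draws, rendering, PAT sampling, weight
  initialisation, shuffling) flows from explicit integer seeds; reruns
  are bit-identical, and the RNG state of the session is restored after
  each seeded operation.

## Known limitations

Phantoms are convex and axis-aligned-ellipsoidal by family; the convex
outline assumption in FLP and the caliper width would bias strongly
non-convex fruit. Intensity is piecewise-stationary; there is no partial
volume model, so sub-voxel wall features are invisible. The network is
validated at desk scale; full-scale (1000², 200-epoch) training is
expressible in the same `unet_config` but is a multi-hour CPU job. The
composite score's weighting convention is one of several in use; ranks
should be compared only within one convention.
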