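---
title: "Indirect and direct volumetry of stroke lesions on diffusion-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect and direct volumetry of stroke lesions on diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Acute ischemic stroke (AIS) lesions are hyperintense on diffusion-weighted
MRI (DWI, b = 1000 s/mm²), and the infarct volume in cc is a direct input
to treatment decisions (thrombectomy and thrombolysis eligibility windows
are phrased in volume thresholds such as "< 70 mL"). Manual segmentation
by a neurologist is slow and subjective; `strokevol` automates the
segmentation-to-volume chain and quantifies how well it does so.

Two routes are implemented:

* **Indirect (2D)** — the volume is split into axial slices; each slice,
  stacked with its two neighbours as a three-channel image, is segmented
  by a 2D encoder–decoder network; the predicted binary pixels are counted
  across all slices and converted to physical volume through the DICOM
  header geometry.
* **Direct (3D)** — the volume is tiled into fixed-size 3D patches, each
  segmented by a 3D encoder–decoder network; overlapping probability maps
  are averaged, binarized, and the 3D mask is measured.

The indirect route turns each patient into many training samples and
always sees the full brain cross-section; the direct route sees true
volumetric context but, with small multifocal lesions, many patches
contain no lesion at all, and the resulting class imbalance degrades
training. The package reproduces this qualitative ordering on synthetic
phantoms.

## The volumetry model

Segmentation runs at a fixed model resolution (256 × 256 by default;
acquisitions range 256–512). Rather than upsampling predicted masks back
to native resolution, the volumetry absorbs the resize into per-pixel
*scale factors*: with an original matrix H × W at pixel spacing
(s_row, s_col) mm and a resized mask H_r × W_r,

    sfw = s_col · (W / W_r),   sfh = s_row · (H / H_r)

are the physical side lengths (mm) of one resized-mask pixel. With the
through-plane spacing s_i (SpacingBetweenSlices when the header carries
it, else SliceThickness), one counted pixel represents

    V = sfw · sfh · s_i   (mm³)

and the patient's lesion volume is `P · V / 1000` cc, where
`P = Σ_n Σ_h Σ_w p(h, w, n)` is the total count of predicted pixels over
all slices. The scale factors must carry physical units for V to be a
volume; defining them as spacing × size-ratio is the only unit-consistent
reading, and it makes the estimate *exact* (bit-identical to the
voxel-count oracle) when no resize occurred. Area is conserved under the
resize: `sfw · sfh · (H_r · W_r) = (s_col · W) · (s_row · H)` exactly
when the model resolution is a power of two, which is why the tests and
the acceptance script restrict resize targets to powers of two while
leaving the acquisition matrix arbitrary.

Two header fields can describe the through-plane geometry. The package
prefers `SpacingBetweenSlices` (the centre-to-centre distance, correct
when inter-slice gaps exist) and falls back to `SliceThickness`; the
phantom generator and the brute-force oracle follow the same rule so the
two ends of every comparison agree by construction.

## The segmentation networks

Both networks are symmetric encoder–decoders with skip connections: each
level applies two (convolution, batch normalization, ReLU) units with
3-voxel kernels, non-bottleneck levels are followed by 2× max pooling,
and the decoder mirrors the encoder with 2× up-convolutions, concatenating
the matching encoder features before each decoder level. A final 1×1
convolution and sigmoid yield a per-voxel probability. The 2D variant
takes three input channels (previous/current/next slice, edge slices
replicated); the 3D variant takes one channel. Everything is implemented
in vectorized R (im2col gathers + BLAS matrix products) with analytically
derived backward passes, verified against finite differences in the test
suite for both dimensionalities.

Training minimizes the soft Dice loss

    L = 1 − 2 Σ(y·p) / (Σy² + Σp² + ε)

reduced over each batch item and averaged, with ε = 10⁻⁶ added to the
denominator only: this avoids 0/0 on empty masks without biasing
nonempty items, and an ε = 0 mode exposes the analytic cases (perfect
overlap → 0, disjoint → 1, the uniform-0.5 worked example → 1/3). A
consequence worth knowing: with a denominator-only ε an empty-label item
has constant loss 1 and contributes no gradient, so false positives on
lesion-free patches are not penalized during training — one ingredient of
the direct path's imbalance problem.

Optimization is Adam (lr 10⁻³ by default), with per-epoch training and
validation Dice loss recorded and the lowest-validation-loss epoch kept.
Patients are split 8:1:1 into train/validation/test by seeded shuffle;
the split is per *patient*, never per slice, so adjacent slices of one
subject cannot leak across splits. Inputs are z-scored per volume
(configurable). Augmentation draws an independent horizontal flip,
vertical flip and k × 90° rotation per item and applies the identical
transform to image and mask; these are pixel permutations, so foreground
counts and binarity are invariant, and each draw has an exact inverse —
both properties are asserted over random draws.

## Patch handling

Direct-path volumes are tiled into patches of a configured shape
(64 × 64 × 16 at 256² resolution; a quarter of the in-plane matrix). For
*training*, tiles are non-overlapping — overlap would only duplicate
samples at epoch cost. For *inference*, patches slide at 50% overlap and
overlapping probabilities are averaged with an online mean
(`m += (v − m)/n`), which — unlike sum-then-divide — reproduces a
constant probability field bit-exactly and still covers every voxel (a
final patch is inserted per axis when the stride does not divide the
volume). Volumes smaller than the patch are zero-padded and cropped back
after stitching. No foreground-biased patch sampling is applied by
default: the class imbalance of uniform tiling is part of what the
direct/indirect comparison measures (a switch exists for users who want
it).

The binarization threshold is 0.5 (configurable), applied after slice
restacking (indirect) or stitching (direct).

## Evaluation metrics

Per-patient pixel tallies (TP, FP, FN, TN) feed:

* sensitivity TP/(TP+FN);
* **`specificity_as_printed`** TP/(TP+FP) — some published
  stroke-segmentation results report this formula under the name
  "specificity", although it is conventionally precision/PPV; the package
  implements it verbatim under an explicit name and additionally reports
  the conventional TN/(TN+FP) as `true_specificity`, making no guess
  about intent;
* F1 (harmonic mean of precision and recall) and Jaccard TP/(TP+FP+FN),
  linked by `J = F1/(2 − F1)`;
* volume similarity `VS = 1 − |FN − FP|/(2TP+FP+FN)`, equal to the
  set-cardinality form `1 − ||m|−|g||/(|m|+|g|)`; VS compares volumes
  irrespective of localization — equal pixel counts give VS = 1 even with
  zero overlap;
* MAE, the mean over patients of |estimated − true| volume in cc.

Rates are macro-averaged over patients; patients with an empty label
(controls) have degenerate denominators, are flagged, rated 0, and are
excluded from the macro averages by default — control cohorts are
assessed through MAE instead, which is exactly how a lesion-free cohort
with an all-background predictor yields MAE = 0. Pooled-pixel aggregation
is available as an alternative mode.

## The phantom generator

Real stroke DWI cohorts are private; the generator produces studies with
*exactly known* ground truth so every stage is testable. A phantom is an
ellipsoidal uniform-intensity "brain" containing hyperintense ellipsoidal
lesion blobs (optionally roughened by a low-frequency radial
perturbation), plus additive Gaussian noise, quantized to the 16-bit
integer grid so DICOM storage round-trips bit-exactly. A voxel belongs to
a blob iff its centre satisfies the implicit-surface inequality — an
unambiguous rule an independent oracle can recompute. Defaults follow a
typical stroke protocol: 256 × 256 matrix over a 220 mm field of view,
24 slices of 3 mm. Cohort sampling draws lesion radii log-uniformly
(volume scales with radius³, so a uniform draw would almost never produce
the clinically important sub-cc regime); with radii spanning 2–20 mm a
40-phantom cohort contains both sub-cc and > 10 cc lesions. What the
phantom does *not* emulate: DWI contrast physics, Rician noise, susceptibility
artifacts, anatomy. Passing tests therefore demonstrate the correctness
of the pipeline's arithmetic and the learnability of hyperintense blobs,
not clinical-grade segmentation accuracy.

## Problem sizes used by tests and the acceptance script

The recovery experiments run a deliberately small version of the study
design: 40 phantoms at 64 × 64 in-plane (10–14 slices, 1 mm pixels, 3 mm
slices), split 32:4:4 per the 8:1:1 ratio; the 2D model (depth 3, 8 base
channels, three-channel input) trains 8 epochs and the 3D model (patch
8 × 16 × 16, the in-plane quarter-matrix default scaled to this
geometry) 4 epochs — a direct-path epoch costs about twice an indirect
epoch here, so the two routes receive matched wall-clock compute, with
model selection by validation loss in both. These sizes give a task that is learnable to high Jaccard on a
single CPU core in minutes while preserving the structural contrast
between the two routes — including the direct path's occasional failure
on the smallest lesions, where patches containing lesion voxels are rare.

## Known limitations

* The DICOM layer reads/writes single-frame Explicit-VR-Little-Endian
  series only (the geometry tags volumetry needs); enhanced multi-frame
  objects, compressed syntaxes and sequence elements are out of scope.
* Training is CPU-bound R; it is sized for method validation, not for
  256² clinical cohorts.
* Transfer learning is supported only as a weight-loading hook
  (`load_pretrained_weights()`); no pretrained weights ship with the
  package.
* Per-lesion (connected-component) volumetry is not the reported
  quantity; the per-patient scalar sums all predicted pixels.
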