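---
title: "Locating bregma and lambda: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating bregma and lambda: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Stereotactic neurosurgery in rodents places probes relative to two skull
landmarks: **bregma**, where the sagittal and coronal sutures meet, and
**lambda**, where the sagittal and lambdoid sutures meet.  `skullmark`
localizes both points in overhead photographs of the skull with a
two-stage pipeline, and ships a synthetic scene generator that makes
every stage testable without any photograph.

## The two-stage model

Working directly on a 2448 x 3264 photograph is wasteful: the skull
occupies a small fraction of the frame.  Stage one therefore detects the
skull bounding box in a 4x-downsampled image (612 x 816), maps the box
back to full resolution, and cuts a fixed 640 x 640 crop centred on it.
The crop is area-downsampled by an exact factor 2.5 to the 256 x 256 x 3
network input.  Stage two regresses a 256 x 256 x 2 *heatmap* pair — one
channel per landmark — and decodes each landmark as the argmax of its
channel, mapped back through the crop geometry.

### Heatmap labels

Each training label channel is an un-normalized 2-D Gaussian centred on
the landmark:

$$ L(p) = \exp\!\left(-\frac{\lVert p - \mu \rVert^2}{2\sigma^2}\right),
   \qquad \sigma = 20 \text{ px (net frame)} $$

truncated to zero beyond $3\sigma$.  Regressing this surface with MSE
carries more information than a binary mask: the loss gradient tells the
network not only *that* it missed but *by how much*.  Two label choices
are not dictated by the regression itself and are fixed here once: the
peak is 1.0 (MSE is scale-covariant, so any positive amplitude trains
equivalently), and the truncation at $3\sigma$ (keeps >98.9% of the mass
and makes sparsity testable).  Labels are always regenerated analytically
in whatever frame they are needed — they are never resampled from
pixels, which would blur the supervision.

Decoding is integer-pixel argmax with ties broken at the smallest
row-major index; sub-pixel refinement is deliberately out of scope.  The
default decodes at net resolution and scales coordinates by 2.5; a
`decode = "upscale_argmax"` flag reproduces the alternative order
(bilinearly upscale the heatmap to 640, then argmax), which differs only
by interpolation smoothing.

### The network

The refinement network is a fully convolutional encoder-decoder built
from bottleneck residual units:

* **Stem** — three 3 x 3 convolutions, 3 → 32 channels; the first has
  stride 2 (the earliest possible reduction saves the most compute,
  which is why the stride sits there rather than later in the stem).
* **Bottleneck blocks** — 3, 4 and 6 residual units with output widths
  128, 256, 512; each block halves the spatial size via stride 2 in its
  first unit (the standard residual-network convention).  A unit
  compresses channels 4x with a 1 x 1 convolution, processes with a
  3 x 3, re-expands with a 1 x 1, and adds a shortcut (identity when
  shapes match, else a projected 1 x 1).
* **Decoder branches** — each block output is restored to full
  resolution by its own chain of stride-2 3 x 3 transposed convolutions
  (2, 3 and 4 steps), halving channels per step, ending in a 1 x 1
  convolution to 2 channels.  The three n x n x 2 outputs are
  concatenated (n x n x 6).
* **Head** — two 3 x 3 convolutions, 6 → 16 → 2.  Every convolution and
  transposed convolution in the network is followed by batch
  normalization and a rectifier *except the last*, which must be free to
  regress the Gaussian surface directly.

Training minimizes MSE over all pixels and both channels with Adam at
its default learning rate 0.001.  Batch size (8) and initialization
(seeded He weights; the final layer scaled by 0.1 so the initial output
is near the mostly-zero labels) are implementation choices fixed for
determinism.  The best-validation-loss checkpoint is kept; validation
uses original (un-augmented) images in inference-mode batch norm.

The network, its gradients and Adam are implemented in the package
itself (C++ im2col kernels behind R graph plumbing); correctness is
enforced by finite-difference gradient tests and a brute-force MSE
oracle in the test suite.

### Stage-one detectors

Skull detection sits behind a one-function interface (`predict_roi`), so
any external object detector can be plugged in.  Two implementations are
bundled:

* a **rule-based baseline**: grayscale, Gaussian smooth, subtract a
  coarse illumination estimate (uncontrolled lighting otherwise shifts
  the threshold), Otsu threshold, largest connected component.  On
  synthetic scenes it is a deterministic, training-free oracle.
* a **convolutional box regressor**: a small stride-2 network with a
  linear head predicting (centre, log-size), trained with Adam/MSE on
  annotated low-resolution images.  It accepts only the resolution it
  was trained at, by design.

The crop window is always the fixed 640 square translated the minimum
distance needed to stay inside the image (never shrunk — the network
needs a fixed input size); images smaller than the crop are
edge-replicated.

### Augmentation and cross-validation

Training images are augmented by composing a crop-window shift (uniform,
±10% of the crop size per axis), a rotation about the crop centre
(uniform over the full circle, since the photographed orientations are
uncontrolled), and horizontal/vertical flips (probability 0.5 each).
Landmarks are transformed by the same analytic composition and labels
regenerated; a draw that would push a landmark out of the crop is
redrawn, up to a cap.  The shift is implemented as window-shifting
within the full image (so no synthetic border enters the crop), with the
rotation interpolating bilinearly under edge replication.  100 copies
per image expand 80 training images to 8000.

Cross-validation uses 5 subsets: subset 5 (13 images) is a fixed test
set; folds 1-4 rotate validation over subsets 1-4 (20 originals each)
and train on the remaining three subsets' augmentations (60 x 100 =
6000 items per fold).  The manifest records every image's role per fold;
test images never enter any training or validation set.

### Evaluation

Errors are Euclidean distances per landmark, reported in the **crop
frame** (full-resolution pixel pitch).  The micrometre conversion is
calibrated per dataset from the mean ground-truth bregma-lambda pixel
distance against a physical distance of 4.2 mm (about 163 px at full
resolution, i.e. ~25.7 um/px), with an override for a fixed value.
Each error is also decomposed into signed components along the
tail-head axis (the normalized ground-truth bregma-minus-lambda
direction) and its left-right perpendicular; the squares reconstruct
the squared error exactly.  Scenes where stage one finds nothing are
tallied as failures and excluded from the means rather than assigned a
penalty distance.

## The synthetic scene generator

The generator is parametric-geometry-first: bregma and lambda are points
on parametric suture curves, fixed before any pixel is rendered, so the
stored annotation is exact by construction.  A scene consists of

* a darker background with low-frequency texture and a linear lighting
  ramp of random direction and strength (lighting is uncontrolled in the
  application);
* a bright, egg-shaped skull outline at a uniformly random orientation —
  the transverse half-width shrinks towards the anterior (nasal) end,
  the gross head/tail asymmetry every real skull photograph shows, and
  the cue that makes the bregma/lambda identities learnable at network
  resolution;
* a sagittal midline suture with a small wobble that vanishes at both
  landmarks, a coronal suture crossing it exactly at bregma (a smooth
  arc bowing anteriorly) and a lambdoid suture crossing exactly at
  lambda (a chevron sweeping caudally);
* optionally, dark vessel-like distractor curves along the midline
  (vessels near the sagittal suture are a known confuser), plus additive
  Gaussian pixel noise.

The bregma-lambda distance is drawn uniformly from 140-190 px in the
crop frame, centred near the ~163 px the calibration assumes.  Intensity
levels (background ~50-80, skull ~165-200 on the 0-255 scale), suture
stroke width (sigma 2.5 px) and noise (sd 5) are free choices of the
generator, picked once to resemble well-exposed photographs; they are
emulation parameters, not calibrated claims about any real camera.

What the generator does *not* emulate: fur and skin at the incision
margin, specular glints, moisture, camera blur and perspective, and real
suture meander.  Passing the synthetic suites therefore demonstrates
that the pipeline's geometry, supervision and optimization are correct
and that the architecture can learn this family of scenes — it does not
certify photograph-level accuracy.

## Presets and problem sizes

All resolution constants live in two presets:

| preset | canvas | lowres | crop | net | width | sigma (net px) |
|--------|--------|--------|------|-----|-------|-------|
| `full` | 2448 x 3264 | 612 x 816 | 640 | 256 | 1 | 20 |
| `tiny` | 612 x 816 | 153 x 204 | 160 | 64 | 1/4 | 5 |

The tiny preset divides every length by 4 (keeping the crop/net scale at
exactly 2.5) and every channel count by 4.  The package's self-checks
run the *tiny protocol*: 200 training crops from independent scenes, 20
validation and 20 held-out scenes, 30 epochs, batch 8, seed fixed.  On
one CPU this trains in a few minutes and reaches a held-out mean
localization error of roughly 1.5-3.5 net pixels per landmark, seed
dependent — the residual spread comes from occasional bregma/lambda
identity confusions on near-ambiguous scenes, not from diffuse
inaccuracy (the acceptance script recomputes the exact numbers).  The
label-width sweep repeats the
protocol with the 256-frame-equivalent sigma of 5 px (1.25 net px):
such a narrow target carries too little gradient information and trains
markedly worse than the 20 px default — the direction the full-scale
study also reports.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)` at pixel centres in every frame;
  net-to-full mapping is `full = origin + coord * 2.5`, exact in
  floating point for all integer (decodable) coordinates.
* Downsampling is area-weighted (mean-preserving; exact for the integer
  factor 4 and the rational factor 2.5 alike).
* Argmax ties (e.g. an all-constant heatmap) resolve to the smallest
  row-major index, deterministically.
* Gaussian labels of centres outside the grid write only the in-grid
  tail; an all-zero channel decodes to (0, 0) by the tie rule.
* Degenerate detector output (zero-area or out-of-bounds boxes), frame
  mismatches, untrained models, empty training sets and impossible
  splits raise typed conditions (`skullmark_*`) rather than propagating
  NaNs.

## Known limitations

* The heatmap FCN trains on CPU at tiny-preset sizes; full-preset
  training (256-net, full width) is supported by the same code but is a
  GPU-scale workload.
* Argmax decoding quantizes predictions to the net grid; in the crop
  frame this contributes up to ~1.8 px of unavoidable error at scale
  2.5.
* The single-detection contract assumes exactly one skull per image.
* Synthetic-data results transfer to photographs only to the extent the
  scene model captures them; see the generator section above.
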