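---
title: "Four-chamber echocardiogram segmentation with heuristic correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-chamber echocardiogram segmentation with heuristic correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Apical four-chamber echocardiography shows both ventricles (upper part of
the scan sector) and both atria (lower part) in a single B-mode plane.
Automatic segmentation of all four cavities is hard: speckle — the
multiplicative, spatially correlated noise intrinsic to coherent ultrasound
— obscures boundaries, clinical screen captures carry burn-in artifacts
(text, ECG traces, patient data) outside the scan cone, and
left-ventricle-centric tools ignore the right heart, whose measurements
matter for diagnosing conditions such as pulmonary hypertension.

`echoseg` implements a three-stage pipeline for this problem:

1. **Cone handling** — refine a scan-sector mask and zero everything
   outside it, removing the burn-in artifacts.
2. **Chamber segmentation** — a U-Net encoder–decoder with batch
   normalization after every convolution assigns each pixel one of five
   classes (background, left ventricle, left atrium, right ventricle,
   right atrium; classes 0–4).
3. **Heuristic correction** — an anatomically motivated post-processor
   detects a ventricle mask that extends below the top of its same-side
   atrium and clips it when the chamber-extreme distance exceeds a
   side-specific threshold.

Everything runs on synthetic speckle phantoms, so no clinical data is
required to exercise, train or evaluate the pipeline end to end.

## Coordinate and label conventions

Indices are 0-based in all user-facing coordinates; the row index `y`
increases downward and a pixel coordinate is written `(x = column,
y = row)`.  Label maps are integer matrices valued 0–4.  "Left" and
"right" are anatomical class labels; by default the left-heart chambers
are drawn on the image right, as in the clinical display convention.

## The phantom generator

`generate_scene()` draws a scan sector (apex top-center, half-angle 35°,
default 112×112 frames — the resolution of common public echocardiogram
collections) and four elliptical cavities under three constraints that the
rest of the pipeline assumes: each ventricle center lies strictly above its
same-side atrium center, every ellipse lies inside the sector, and rendered
chamber regions are pairwise disjoint.  Placement is rejection-sampled; a
geometrically impossible configuration (e.g. a 1° sector) raises an error
naming the violated constraint.

Chamber geometry fractions were fixed once to mimic a four-chamber view in
which the chambers span most of the sector depth: ventricle centers near
0.44 of the frame height with vertical semi-axes of 0.12–0.145, atrium
centers near 0.76 with semi-axes 0.085–0.11, lateral columns at 0.40/0.60
of the width.  Cavities are darker (intensity 0.06–0.18) than the
surrounding tissue (0.55), as in B-mode imaging.

`render_phantom()` applies multiplicative speckle inside the cone: a
unit-mean Rayleigh field, mixed in with weight `speckle_scale` (default
0.35) and smoothed with a Gaussian of σ = 1 px so the noise is spatially
correlated, which is the standard first-order B-mode approximation.  With
`speckle_scale = 0` the image is piecewise constant, which the tests use
as a no-noise limit.  Two constant-intensity horizontal strips above the
apex emulate text/trace burn-ins.

`inject_leak()` manufactures the defect the corrector exists for: a
connected protrusion of a chamber mask that runs toward (and past) the
adjacent same-side chamber, overwriting only background pixels.  This
imitates a prediction in which the right ventricle mask wraps around the
right atrium.

**What the phantoms do not emulate:** wall/valve texture, probe-dependent
point-spread functions, Doppler overlays, temporal cardiac-cycle dynamics
(frames are independent stills) and inter-observer annotation variability.
Tests passing on phantoms therefore demonstrate that the implementation is
correct and that the training recipe converges on data with the assumed
statistical structure — not that the trained weights transfer to clinical
recordings.

## Cone refinement

A detected cone mask is refined by keeping its largest connected
component, closing then opening with a 5 px disc (boundary low-pass), and
filling interior holes; dilation with a 3×3 box (default 2 iterations)
then improves the sector corners before `apply_cone()` zeroes everything
outside.  The structuring-element sizes are package choices — the effect
required is a regular cone-beam shape, and these are the smallest standard
elements that achieve it on 112–128 px frames.  `extract_cone_geometric()`
is a weight-free stand-in for a learned cone detector: Otsu threshold,
largest bright component, filled convex hull (a sector is convex, so the
hull recovers it including the dark cavities).  Users with an external
detector can supply its mask instead.

## The network

`unet_spec()` describes the reference architecture: 128×128×1 input, four
contraction blocks of 16/32/64/128 channels (two 3×3 convolutions each,
then 2×2 max-pool), a 256-channel bottleneck, a mirrored expansion path
(2×2 stride-2 transposed convolutions, skip concatenation, two 3×3
convolutions), an 8-channel penultimate 3×3 convolution and a 1×1
classification convolution.  Per operation the order is convolution →
rectifier → batch normalization, including after the final 1×1
convolution.  That trailing rectifier+normalization before a softmax head
is unusual; the package implements it as specified because the per-block
parameter counts pin it down (a 1×1 convolution from 8 channels to `n`
classes with bias and batch norm has `11n` parameters, and the reference
count of 55 forces `n = 5` — which is also how the class count, never
stated explicitly, is derived).  Transposed convolutions carry a bias but
no batch norm (262,400 = 4·256·256 + 256 only fits a 2×2 kernel with bias).

`audit_parameters()` counts parameters from the actual tensor shapes and
`audit_reference()` recomputes them from the closed form
(`9·c_in·c_out + 3·c_out` for 3×3 conv+BN, `c_in·c_out + 3·c_out` for the
1×1, `4·c_in·c_out + c_out` for the transposed convolutions); the default
network totals 2,315,135 trainable parameters.

Because no deep-learning framework is part of this package's dependency
set, the network is implemented natively in C++ (single precision):
im2col + GEMM convolutions in a channels-last layout, exact
batch-normalization backward, max-pool argmax routing, and the input
gradient computed as a direct convolution with the spatially flipped
kernel.  The implementation is validated by central finite differences on
a tiny network (relative error below 3% at the float32 noise floor) and by
the parameter audit.

Numerical choices: batch-norm ε = 1e-5 and running-statistics momentum
0.1; Adam moment decays 0.9/0.999 with ε = 1e-8; weight initialization is
fan-in uniform `U(±1/√fan_in)` from one integer seed; arg-max ties break
to the lowest class index (so an all-zero classifier yields background
everywhere, which the tests exploit); inference uses running statistics.
On load the package pins the BLAS thread pool to one thread unless
`OPENBLAS_NUM_THREADS` is set, keeping results bit-reproducible.

## Training protocol

`preprocess()` resizes frames bilinearly to 128×128 and normalizes 8-bit
intensities to [0, 1]; label maps are resized nearest-neighbor, the only
label-safe interpolation.  `split_dataset()` partitions items 80/10/10
(floor allocation, remainder to train, deterministic per seed).  `fit()`
runs mini-batch Adam — batch 8, fixed learning rate 1e-3, per-pixel
multiclass cross-entropy, reshuffling every epoch — and records, per
epoch, the training loss, validation loss and validation Dice/IoU/mean
pixel accuracy.  No augmentation, class weighting, early stopping or
best-epoch selection: final-epoch weights are the model.

The package's reference experiment trains on 100 phantoms (80/10/10 after
the split) for 50 epochs — a problem size at which the seeded run finishes
in well under half an hour on one CPU core while leaving the protocol
itself untouched; larger phantom sets train the same way (the generator
takes any `n`) and converge to the same near-perfect held-out Dice.  The
test suite asserts a conservative Dice ≥ 0.85 together with a
non-increasing 5-epoch moving average of the training loss and the
co-movement of validation Dice and IoU.  Validation metrics are macro
averages: computed per image (and per chamber class), then averaged —
chosen over pixel-pooling because per-frame averages are how segmentation
quality is usually reported for image sequences; the convention is stated
in every report.

## Heuristic correction

For each side independently, the corrector takes the ventricle and atrium
masks (each reduced to its largest connected component — the remedy for
fragmented predictions), and:

1. **Overlap test:** flags the side if the ventricle's maximum `y` strictly
   exceeds the atrium's minimum `y`.
2. **Extreme distance:** measures the Euclidean distance between the
   ventricle's topmost pixel and the atrium's bottommost pixel — the two
   most extreme points of the pair, spanning the combined vertical extent
   of the two chambers.  Ties on the extreme row resolve to the smallest
   column for determinism.
3. **Cut:** if the distance exceeds the side threshold — 68.5 px on the
   right, 76.5 px on the left — every ventricle pixel with row index at or
   below the atrium's top row is removed.  Smaller overlaps are regular
   anatomical overlap and are deliberately left alone.  A cut that would
   erase the whole ventricle signals a pathological prediction; it is not
   applied and is flagged in the report instead.

The extreme-point reading (one extreme per mask, ventricle top vs atrium
bottom) is a documented interpretation: it reproduces the reference worked
example — points (54, 9) and (45, 80) give a distance of 71.6 at one
decimal, which exceeds 68.5 and fires the right-side cut — and it measures
the overall size of the heart on that side, which is what makes a fixed
threshold meaningful ("small heart ⇒ any overlap is probably regular").
The alternative reading (ventricle bottom vs atrium top) would only
re-measure the overlap depth that the overlap test already captures.  The
cut row is likewise unstated upstream; removing rows ≥ the atrium top is
the simplest rule consistent with the overlap test.  After a cut the
overlap test is false by construction, so the corrector is idempotent; it
only ever removes pixels, and it never touches the other side's classes.

The thresholds are defined in pixels of the 128×128 working frame.  For
label maps at other resolutions they are rescaled by the ratio of frame
diagonals — a package convention, since the resolution at which they were
originally tuned is not stated.

`erode_for_display()` erodes every chamber mask with the same 3×3 element
(1 iteration by default, the conventional default of morphological
libraries) purely for visualization; for congruent shapes equal erosion
preserves area ratios exactly, which the tests check on squares.  For
general shapes ratio preservation is only approximate and is not asserted.

## Metrics

`dice()` (2|A∩B|/(|A|+|B|)), `iou()` (|A∩B|/|A∪B|), overall and per-class
`pixel_accuracy()` (per-class accuracy is the class recall), and
`mean_pixel_accuracy()` (mean recall over the classes present in the
reference, background included).  Empty-vs-empty mask pairs score 1.0 so
frames where a chamber is absent from both prediction and reference do not
drop out of averages — a convention the package fixes because the upstream
definition is silent.  `compare_correction()` tabulates per-chamber Dice
before and after correction over a full frame set and a flagged subset,
mirroring the before/after analysis that motivates the corrector.

## Design decisions taken where the design was open

- Speckle model: unit-mean Rayleigh × Gaussian-blur, the standard B-mode
  first approximation; only the noise's name is prescribed upstream.
- Class count 5 derived from the 55-parameter final operation.
- Transposed-convolution kernel 2×2 with bias and no batch norm, forced by
  the 262,400 count.
- Nearest-neighbor label resizing; bilinear for frames.
- Macro (per-image) metric averaging; documented in report headers.
- Cut row at the atrium's top row; threshold rescaling by frame diagonal.
- Largest-component reduction per chamber class before correction.
- PNG label maps are written with raw class ids 0–4 as 8-bit gray values
  (no palette support in the PNG writer used); they read back exactly.

## Known limitations

- Phantoms are stills of idealized ellipses; no cardiac dynamics, no
  realistic myocardial texture, no fan-line or reverberation artifacts.
- The geometric cone extractor assumes the sector is the largest bright
  structure after thresholding; screen captures with large bright overlays
  would need an externally supplied cone mask.
- The corrector only fixes ventricle-past-atrium overlap; it cannot repair
  left/right swaps or missing chambers, and it never adds pixels.
- Training is CPU-bound single precision; at clinical dataset scale a GPU
  framework would be the appropriate engine, with this implementation as
  the reference semantics.
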