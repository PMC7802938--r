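---
title: "Methods: the segmentation network, the trait definitions, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the segmentation network, the trait definitions, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plantunet segments individual maize shoots in top-view images taken at the
seedling stage (V3 and V6, roughly two and four weeks after sowing) and turns
each segmented shoot into a vector of morphological and colour traits. This
vignette explains the model, the trait definitions, the numerical choices
that were genuinely open, and what the synthetic benchmark does and does not
demonstrate.

## The segmentation model

The network is a compact three-level U-net variant. The contracting path has
three downsampling modules, each a 3×3 same-padded convolution (32, 64, 128
filters) with Leaky ReLU activation followed by 2×2 max pooling; max pooling
is used deliberately because it preserves edge responses, which matter for
the outline-based traits downstream. The bottleneck applies two further 3×3
convolutions (256, then 128 filters) and a dropout layer. The expanding path
mirrors the encoder: each upsampling module is a 2×2 stride-2 transposed
convolution, channel-wise concatenation with the matching encoder feature
map, and the listed 3×3 convolutions (128/64, 64/32, 32) that reduce the
fused feature dimension. A final 1×1 convolution with a sigmoid produces a
single-channel foreground probability map the same size as the input
(`network_shapes(network_config())` prints the full layer table). Training
minimizes mean pixelwise binary cross-entropy with Adam at learning rate
1e-4 and batch size 1.

Activations: hidden layers use Leaky ReLU, `f(x) = x` for `x >= 0` and
`theta x` otherwise, so that units keep a gradient when inactive; the output
layer uses the logistic sigmoid, which maps any real number into (0, 1) and
matches the two-class pixel labelling.

Choices the architecture description leaves open, and what this package
does:

* **Leaky slope theta.** Not specified; default 0.01, exposed in
  `network_config()`.
* **Dropout placement and rate.** Only "a dropout layer is added" is
  specified. We place a single dropout layer (rate 0.5) after the bottleneck
  convolutions — the bottleneck carries the most parameters, so that is
  where small-sample overfitting concentrates. Placement cannot be recovered
  from the architecture table; the rate and position are configurable.
* **Final kernel.** The layer table prints a 3×3 final filter while the
  accompanying text says a 1×1 convolution acting as the fully connected
  output; both give identical shapes under same padding. We follow the text
  (1×1); `final_kernel = 3` restores the table reading.
* **Upsampling operator.** "Up sampling convolution" is read as a 2×2
  stride-2 transposed convolution (learned), not fixed interpolation.
* **Skip fusion.** "Fused with the low-level feature maps" is implemented
  as channel concatenation, the U-net lineage's convention, consistent with
  the post-fusion convolutions being described as reducing the feature
  dimension.
* **Loss clipping.** Predictions are clipped to `[1e-7, 1 - 1e-7]` inside
  the cross-entropy to guard the logarithms.

The implementation is a purpose-built conv-net engine (im2col GEMM
convolutions, pooling with argmax bookkeeping, non-overlapping transposed
convolution) in RcppArmadillo, with the backward pass verified against
central finite differences in the test suite.

## Training protocol

The annotated corpus is expanded exactly fourfold before training: each
image/mask pair contributes the original plus one mirrored, one translated
and one rotated variant (so 128 pairs become 512). Translation offsets are
drawn uniformly up to ±10% of each dimension with zero fill; rotations are
drawn from {90°, 180°, 270°} so masks stay exact under the quarter-turn
lattice. During training, every drawn sample is additionally passed through
a random elastic deformation: a 3×3 grid of independent 2-D displacements
drawn from Normal(0, sigma²) with sigma = 10 px is interpolated smoothly
(cubic splines) to full resolution and used to warp image (bilinear) and
mask (nearest neighbour, preserving binarity) identically. The deformation
is area-preserving in expectation; over 100 seeded deformations of a compact
blob the typical area change is ~7% and individual draws can reach ~20%.

Epochs contain 200 batches of size 1 drawn with replacement (the corpus
gives no consumption order, so sampling with replacement is the stated
guess). "Train until the validation loss is stable" is operationalized as
patience-based early stopping: stop after 20 epochs without an improvement
of at least 1e-4, cap at 500 epochs, and return the parameters of the best
validation epoch.

## Inference on arbitrary image sizes

Plot mosaics are larger than the 256×256 training tile. `segment_image()`
slides the network over the image with a configurable overlap (default
32 px), averages probabilities wherever tiles overlap, reflection-pads the
borders (and pads images smaller than one tile up, cropping afterwards),
then thresholds at 0.5. The threshold and the 8-bit `[0, 1]` intensity
normalization are defaults of this package, not prescriptions. Averaging in
overlap zones suppresses tile-seam artifacts. Note that same padding makes
the network's output position-dependent within a tile even on constant
input, so tile-offset invariance is exact only for spatially constant
output fields; the suite pins the averaging arithmetic down in exactly that
setting.

## Trait definitions

All coordinates are 0-based (row, col) with the origin at the top-left.
Plants are the 8-connected components of the binary mask with area at least
`min_area` (default 50 px; the filter is what rejects small weed blobs),
each with its outer contour traced by Moore-neighbour tracing.

* **Coverage** is the foreground pixel count of the component; with a
  calibration (cm per pixel edge, from size-known markers in the scene) it
  converts to cm² by multiplying with the squared pixel size.
* **Circumscribed radius** is half the maximum pairwise distance between
  contour pixels, computed exactly via the convex hull (the farthest pair
  lies on it). Note this half-diameter is not the minimum-enclosing-circle
  radius: for any planar set `r <= R_mec <= 2r/sqrt(3)` (Jung's bound), and
  the suite enforces that relation. The half-diameter definition is the
  normative one here.
* **Aspect ratio** is the x-extent over the y-extent of the axis-aligned
  bounding box, each extent counted as `max − min + 1`. It is deliberately
  axis-aligned — the extents are defined along the image axes — so unlike
  the radius it is not rotation-invariant.
* **Azimuth-plane angle.** Expanded maize leaves lie along a vertical
  plane whose top-view trace is a line. We fit that line as the principal
  axis (leading eigenvector of the 2×2 pixel-coordinate covariance): it is
  deterministic, parameter-free, and uses all foreground pixels rather than
  a clustering heuristic. β is the angle between the axis and the
  north–south reference, folded to [0, 180). The default reference is the
  image x-axis (acquisition convention: image left = north) and is
  configurable. When the coordinate covariance is nearly isotropic
  (eigenvalue ratio < 1.2) no azimuth plane is defined; the value is
  returned but flagged.
* **Colour traits** are the per-channel means of R, G, B over the plant's
  pixels, and the means of the per-pixel HSV conversion (H in [0, 360), S
  and V in [0, 1]). Hue is averaged circularly (vector mean) to avoid the
  0/360 wrap artifact; a flag restores the plain mean.

## Agreement statistics

Automatic trait values are compared against manual measurements with the
coefficient of determination about the manual mean,
`R² = 1 − Σ(vᵢ − v′ᵢ)² / Σ(vᵢ − v̄)²`, and the RMSE normalized by the manual
mean (NRMSE, reported as a percent). Two printed-formula issues are resolved
deliberately: the numerator residuals are squared (the only form that is a
coefficient of determination), and although the quantity is called
"adjusted", no predictor count exists in a paired-agreement setting, so the
unadjusted form is used. Group summaries report per-group arithmetic mean
and sample standard deviation per trait; singleton groups report the SD as
missing, not zero.

## The synthetic benchmark

Because the real test imagery and manual measurements are not
redistributable, the package ships a generator that renders ground-truthed
scenes: green multi-leaf rosettes on low-frequency brown soil noise, with
the distractors that make field imagery hard — a dark drip-tape stripe
(probability 0.5), small green weed blobs (0–3 per scene, kept below the
default area filter so the filter, not the network alone, is what rejects
them), and a global brightness factor drawn from [0.7, 1.3]. Each plant is a
rosette of elliptical leaves on alternating sides of a true azimuth plane
β*, with angular jitter sd `45 / concentration` degrees. Scenes are drawn at
one of two growth stages (V3 or V6 scale factors), mirroring the two imaging
time points, which gives the corpus a realistic spread of plant sizes.
Layouts follow a jittered planting grid like a real plot. The mask is
exactly the union of rendered leaf pixels, and the per-plant truth (exact
coverage, exact contour-based radius, exact box extents, β*, realized colour
means) is computed analytically from the rendered pixel sets, independent of
the extraction pipeline.

Ellipse leaves rather than spline blades are a stated fidelity limit: they
keep the analytic truth exact while preserving the geometric difficulty of
the traits. The generator does not model leaf curvature, occlusion between
neighbouring plants, specular soil highlights, or perspective; passing the
synthetic suites therefore demonstrates the correctness of the pipeline and
its recoverability properties, not field-level accuracy.

## Problem sizes used by the test suite

The suite exercises the full-size architecture for the shape audit but
trains a reduced network — 64×64 tiles, encoder filters 8/16/32 (the
bottleneck and decoder widths follow the same pattern as the full
architecture) — for 30 epochs of 200 steps on 64 synthetic scenes, scoring
16 held-out scenes. Two protocol details scale with the tile: the elastic
sigma becomes 2.5 px (10 px at 256, proportional to image size), and the
phenotyping area filter becomes 15 px. Azimuth recovery is measured on 100
single-plant scenes at concentration 25 (angular jitter sd 1.8°, i.e.
leaves nearly coplanar, which is what the azimuth-plane model assumes).
Geometry traits are checked against exhaustive brute-force oracles on 200
random blobs.

## Known limitations

* Training reproducibility is platform-conditional (BLAS reduction order);
  all other outputs (generator, phenotyping, statistics) are bitwise
  reproducible from their seeds.
* The minimum bounding box is axis-aligned by definition; a rotated
  min-area box is a different trait and out of scope.
* No leaf counting, skeletonization, or per-leaf segmentation; no
  test-time augmentation or morphological post-processing of network
  output.
* Whether the original dropout sat in the encoder, decoder, or bottleneck
  is not recoverable from the architecture description; only this package's
  configurable default is provided.
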