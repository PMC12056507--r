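---
title: "Segmenting debris-obscured tumor spheroids: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting debris-obscured tumor spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spheroseg)
```

## Scope and model

Multicellular tumor spheroids imaged in brightfield appear as compact
dark regions on a bright background.  After irradiation or drug
treatment, shed dead-cell debris forms a grainy cloud around the
remaining spheroid that can be larger than the spheroid itself and
locally darker, so intensity thresholding no longer separates spheroid
from background.  `spheroseg` treats segmentation as per-pixel
two-class classification: a convolutional encoder–decoder maps the
8-bit image to a probability heatmap, which a deterministic
postprocessing chain converts into a single spheroid mask and closed
boundary contour.

The network is a plain U-Net-style architecture: `depth` encoder
stages of (3×3 conv → ReLU) × 2 followed by 2×2 max pooling, a
bottleneck, and a mirrored decoder using nearest-neighbour upsampling,
a 3×3 convolution, and concatenation of the matching encoder activation
(skip connection) before a second convolution.  A final 1×1 convolution
emits two class scores per pixel, normalized by softmax.  Channel
width doubles per stage from `base_channels`.  The default desk-scale
model (`depth = 3`, `base_channels = 8`, ≈ 114k parameters) is
deliberately small: it trains in minutes on one CPU, and segmentation
accuracy in this problem family is known to be robust to the choice of
backbone, so the architecture is exposed through `build_model()` rather
than fixed.  Larger pretrained encoders are out of scope because no
external weights are bundled; `encoder_id`/`pretrained` guard that path
explicitly.

All layers, the backward pass, both optimizers and the learning-rate
policy are implemented in the package (R orchestration over
Rcpp/Armadillo im2col + GEMM kernels).  The backward pass is verified
against central finite differences in the test suite.

## Training recipe

* **Loss.** Dice loss (region-based) is the default,
  `1 − (2Σpt + ε)/(Σp + Σt + ε)` with smoothing `ε = 1` in pixel-count
  units; cross-entropy and focal loss (`γ` configurable, `γ = 0`
  reduces focal to cross-entropy) are provided for comparison.
  Probabilities are clipped to `[1e−7, 1 − 1e−7]` before logs.
* **Optimizer.** Adam (default) or RAdam with variance rectification
  wrapped in Lookahead (`k = 6`, `α = 0.5`).  The choice matters little
  here; both are exposed because practitioners compare them.
* **Learning-rate policy.** The 1-cycle schedule ramps linearly from
  `lr_bounds[1]` to `lr_bounds[2]` over the first half of all planned
  steps and back over the second half.  Default bounds `1e−4`–`1e−2`
  were chosen once as a stable range for Dice loss on the synthetic
  data; an automated range test is intentionally not included.
* **Early stopping.** After every epoch the mean Jaccard distance over
  the validation set is computed through the *full* inference path
  (probability map → native-resolution upscale → threshold → largest
  component), not from the loss.  Training stops after `patience = 10`
  epochs (default; the scaled study below uses 8) without improvement
  and restores the best weights.  Training refuses to start if any
  spheroid ID occurs in both training and validation sets.
* **Augmentation.** Each training image is transformed exactly once
  with one of vertical flip, horizontal flip or 180° rotation (chosen
  uniformly), doubling the training set.  These transforms preserve the
  rectangular frame, so no border extrapolation artifacts are
  introduced; arbitrary-angle rotations are excluded for that reason.
* **Resolution.** Images may be downscaled (bilinear) by
  `resize_factor` for the forward pass — half resolution is the
  recommended default trade-off — while masks use nearest-neighbour.
  Probability maps are always upscaled (bilinear) back to the native
  pixel grid *before* thresholding, so every metric is computed at
  native resolution and µm conversions use the native pixel size.

## Postprocessing and metrics

The chain is fixed: threshold at probability ≥ 0.5 (inclusive),
8-connected component labelling with deterministic raster-scan label
order, largest-component selection (ties broken by lowest label), and
Moore border following with Jacob's stopping criterion for the outer
contour.  Holes are ignored; no speckle filter is applied by default
(`min_area = 0`) since the chain itself should be judged unfiltered,
but a minimum area is exposed for noisy probability maps.

Per image the package reports JCD, RDD, RCD, and the average radial
error Δr; a prediction with zero overlap (JCD = 1) is *invalid* — RDD
and RCD are then set to 1 and Δr is computed against the empty
prediction so dataset summaries stay well defined.  Images with extra
predicted components beyond a valid largest spheroid are *ambiguous*.
ISF and ASF are the respective fractions, each with binomial standard
error.  Ambiguity is decided purely by component count (> 1); whether
the extra component overlaps the target is not considered.

Degenerate components with fewer than 3 contour points have perimeter
0; their circularity is defined as 1.0 and flagged, since sub-3-pixel
spheroids are never meaningfully evaluated.  Circularity of digitized
shapes may slightly exceed 1 because the polygonal chain
underestimates the continuous perimeter; values are reported as
computed, not clipped.  The closing segment of the contour is included
in the perimeter.

For interobserver analysis, `interobserver_matrix()` produces the
image × rater-pair JCD table (lexicographic pair order), and
`friedman_test()` / `dunn_bonferroni()` test for systematic differences
between pairs.  The Friedman statistic uses mean ranks with the
standard tie correction and the χ² asymptotic (appropriate for the
typical 10²-image blocks); fully tied tables return 0 by convention.

## The synthetic generator

`synth_config()` defaults emulate a typical acquisition: 1300 × 1030 px
at 2.04 µm/px, 16-bit with background 1300 ± 130 (so the images occupy
under 10 % of the dynamic range, as real brightfield exports do), a
linear illumination ramp (≤ 5 % across the frame), and spheroid
diameters of 200–1000 µm.  The spheroid body is a star-shaped region
`ρ ≤ r(θ)` with a smooth Fourier rim perturbation, renormalized to be
area-preserving so that the drawn diameter *is* the mean diameter of
the emitted mask (up to rasterization); shading darkens toward the
center as a thickness proxy (rim attenuation 0.30, core 0.55).  Debris
is smoothed multiplicative noise clipped to an annulus of
`debris_extent_factor` × spheroid radius whose opacity tapers radially;
above `debris_opacity ≈ 0.6` the darkest debris patches are darker than
the spheroid rim, reproducing the property that breaks thresholding.
With probability `double_spheroid_prob` a second touching spheroid is
added to image *and* target.  Rater masks displace the target boundary
by a smooth random radial field applied to the signed distance
transform.

What the generator does **not** model: physical optics (defocus,
diffraction rims), fluorescence, Z-stacks, semi-transparent spheroids
with visible single cells, and annotation biases of particular human
experts.  Passing the bundled tests therefore demonstrates that the
pipeline, training loop and metrics are correct and that the learned
segmenter solves the debris-vs-spheroid discrimination this generator
poses — not that the small default model matches expert accuracy on
real microscope data.

All randomness flows from one integer seed: each sample derives its own
stream from `(seed, index)`, so any sample is reproducible in
isolation and datasets are order-independent.

## Numerical and interface choices

* 16→8-bit conversion is per-image min–max scaling with round-half-up;
  a constant image maps to all zeros (the rescale is undefined there,
  and zero is the conservative choice).  8-bit inputs are normalized to
  [0, 1] by division by 255.
* Masks are logical matrices indexed `[row, col]` (1-based inside R);
  contour exports are 0-based for interoperability.  Masks serialize as
  0/255 PNG, images as 8/16-bit TIFF, manifests as CSV, reports as
  JSON.
* Split assignment randomizes over spheroid IDs, not images, with
  largest-remainder rounding of the ID counts — the leakage-safe
  reading for time-series data.
* Inference pads inputs by reflection to the next multiple of
  `2^depth` and crops afterwards, so arbitrary image sizes work.
* Foreground connectivity is 8, background 4 (the standard pairing for
  border following); contour points are pixel centers, which biases the
  perimeter of small digitized disks by O(1 px).

## Study sizes used in the bundled checks

The scaled training study (tests and `scripts/acceptance.R`) uses
128 × 128 px frames at 2.04 µm/px, diameters 100–200 µm, moderate
debris (extent 1.8, opacity 0.5), 60 training / 20 validation / 20
test spheroids, the depth-3/8-channel model at half resolution, Dice
loss, batch 2, at most 40 epochs with patience 8.  These sizes were
chosen so the whole study runs in a few minutes on one CPU while still
exhibiting the debris failure mode: on heavy debris (extent 2.5,
opacity 0.9) the Otsu baseline's mean JCD is roughly 2.5× that of the
trained model, while on clean images Otsu alone reaches IoU ≈ 0.95 —
matching the qualitative picture that classical thresholding suffices
without debris and fails with it.

## Known limitations

* The bundled model is desk-scale; matching expert-level accuracy on
  real data requires a larger encoder, pretrained weights and real
  annotated images, all intentionally outside this package.
* Only the outer contour is traced; hole topology and hierarchical
  contours are not represented.
* Moore tracing can visit pixels of 1-px-wide spurs twice; the shapes
  produced by thresholded probability maps are not of this kind in
  practice.
* The Friedman p-value relies on the χ² asymptotic; exact permutation
  tests are not implemented.
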