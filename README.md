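# spheroseg

Segmentation and morphometric analysis of multicellular tumor spheroids
(MCTS) in brightfield microscopy images.

## The problem

Long-term spheroid-based assays monitor large populations of 3-D tumor
spheroids over weeks of imaging to quantify therapy response.  The
analysis hinges on semantic segmentation: identifying the set of pixels
belonging to the spheroid in each image, from which the mean diameter,
projected area, estimated volume and circularity are derived.  Untreated
spheroids are compact and dark with a clear rim and are easy to segment;
irradiated or drug-treated spheroids shed dead cells, and the resulting
debris cloud can cover a far larger region than the spheroid and be
locally even darker, which defeats classical thresholding methods and
demands either laborious manual annotation or a trained segmenter.

`spheroseg` provides that workflow end to end, in R:

* a seeded **synthetic image generator** producing brightfield-like
  16-bit images of debris-obscured spheroids with ground-truth masks,
  rater-jitter masks and time-series manifests, so everything is
  testable without microscope data;
* a trainable **convolutional encoder–decoder segmenter** (U-Net
  family, implemented natively with Rcpp/Armadillo kernels) with Dice,
  cross-entropy and focal losses, Adam and RAdam+Lookahead optimizers,
  the 1-cycle learning-rate policy, and validation-based early stopping
  on the mean Jaccard distance;
* the **postprocessing chain** from probability heatmap to final
  contour: inclusive 0.5 thresholding, 8-connected component labelling,
  largest-component selection and Moore border following to a closed
  polygonal chain — plus a classical Otsu baseline;
* **morphometrics** and a **metric suite** for judging segmentations,
  with interobserver agreement statistics.

## Metrics

For a predicted pixel set *P* and a manually segmented target *T*:

* Jaccard distance, the relative area error:
  `JCD = 1 − |P∩T| / |P∪T|` (IoU = 1 − JCD);
* mean diameter `d_T = 2·sqrt(|T|/π)`, spherical volume `π·d_T³/6`, and
  circularity `4π·|T|/L²` with perimeter `L` from the traced contour;
* relative diameter/circularity deviation `RDD, RCD = |c_P − c_T| / c_T`;
* average radial error
  `Δr = sqrt((|P∪T| − |P∩T|)/π + d_T²/4) − d_T/2`,
  the thickness of a circular layer around a circle with the target's
  area that holds the whole mismatched area (excess and missing pixels
  do not cancel);
* invalid spheroid fraction ISF (predictions with no overlap, JCD = 1,
  for which RDD and RCD are set to 1) and ambiguous spheroid fraction
  ASF (extra components beyond a valid largest spheroid), each reported
  with the binomial standard error `sqrt(p(1−p)/n)`;
* Friedman rank test plus Dunn–Bonferroni post hoc comparisons for
  rater-vs-rater and rater-vs-model agreement tables.

## Worked example

Generate a synthetic cohort of debris-obscured spheroids, train the
small U-Net at half resolution, and evaluate on held-out spheroids:

```r
library(spheroseg)

cfg <- synth_config(image_size = c(128, 128),
                    spheroid_diameter_range = c(100, 200),  # um
                    debris_extent_factor = 1.8, debris_opacity = 0.5,
                    double_spheroid_prob = 0, seed = 0)
train_set <- lapply(1:60, function(i) generate_sample(cfg, i,        spheroid_id = sprintf("TR%03d", i)))
val_set   <- lapply(1:20, function(i) generate_sample(cfg, 1000 + i, spheroid_id = sprintf("VA%03d", i)))
test_set  <- lapply(1:20, function(i) generate_sample(cfg, 2000 + i, spheroid_id = sprintf("TE%03d", i)))

model <- build_model(depth = 3, base_channels = 8, input_size = c(64, 64), seed = 0)
model <- train(model, train_set, val_set,
               train_config(loss = "dice", epochs = 40, patience = 8,
                            seed = 0, augment = TRUE, resize_factor = 0.5))

records <- do.call(rbind, lapply(test_set, function(s) {
  seg <- extract_spheroid(predict_probmap(model, s$image, 0.5))
  evaluate_image(seg, s$target, pixel_size = 2.04)
}))
summarize_evaluation(records)
#> Evaluation over 20 images
#>   JCD        mean 0.0632 (6.3%)  sd 0.0186  median 0.0591
#>   RDD        mean 0.0126 (1.3%)  sd 0.0129  median 0.0095
#>   RCD        mean 0.1054 (10.5%)  sd 0.0254  median 0.0992
#>   delta_r    mean 2.48 um  sd 0.81  median 2.33
#>   ISF        0.0000 +/- 0.0000
#>   ASF        0.0000 +/- 0.0000
```

The mean Jaccard distance of 0.063 means a 6.3 % relative area error on
unseen spheroids; the diameter — the quantity growth curves are built
from — is recovered to 1.3 %, the average radial boundary error is
about 2.5 µm (roughly one pixel at 2.04 µm/px), and every test image
yields exactly one valid spheroid (ISF = ASF = 0).  Morphometrics for a
single segmented image:

```r
s <- test_set[[1]]
seg <- extract_spheroid(predict_probmap(model, s$image, 0.5))
morphometrics(seg, pixel_size = 2.04)
#>   area_px diameter_px diameter_um volume_um3 circularity degenerate
#> 1    3631    67.99362     138.707    1397313   0.7743002      FALSE
jcd(otsu_baseline(s$image), s$target)
#> [1] 0.152
```

On heavy debris (opacity 0.9, extent 2.5× the spheroid radius) the gap
widens sharply: classical Otsu thresholding averages JCD ≈ 0.48 while
the trained model stays around 0.18 — the failure mode that motivates a
learned segmenter.

A shell entry point wrapping the same functions is installed at
`inst/exec/spheroseg` (`generate`, `train`, `segment`, `evaluate`
subcommands); see `?spheroseg_main`.

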