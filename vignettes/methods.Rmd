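---
title: "Methods: thoracic cropping, augmentation and classification of whole-body bone scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thoracic cropping, augmentation and classification of whole-body bone scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectmets)
```

## The problem

Whole-body bone scintigraphy images the uptake of a bone-seeking
radiotracer ([99mTc] MDP) across the skeleton. Each examination records
an anterior and a posterior planar view as a 256 (width) x 1024 (height)
matrix of 16-bit unsigned radiation-dosage counts. Metastatic deposits —
most commonly in the spine and ribs — appear as focal areas of elevated
uptake ("hot spots"), but so do the tracer injection point on an arm and
the bladder, and the images have low spatial resolution and a wide,
patient-dependent dosage range. `spectmets` implements a pipeline that
(1) crops the thoracic region adaptively from the whole-body scan,
(2) augments the cropped images geometrically, (3) trains convolutional
classifiers for the binary normal-versus-metastasis decision, and
(4) evaluates them with the standard diagnostic metrics.

Clinical bone-scan archives are access-restricted, so the package also
ships a first-class synthetic phantom generator with exact ground truth;
all quantitative statements below are computed on phantoms.

## The phantom generator

`generate_scan()` builds a body silhouette from piecewise geometric
primitives: an elliptical head, a neck, a shoulder flare, a trunk with
separate arm bands, a pelvis, and two legs with a thigh bulge. The
silhouette is constructed so that the per-row count of nonzero pixels —
the signal the cropper works from — has the canonical whole-body
structure: three leading peaks (head, then the two upper-trunk flares
conventionally read as the elbow and shoulder positions, with the third
peak marking the top of the thorax) and a third valley at the onset of
the legs, followed by a thigh bump.

Dosage values:

* **Body**: Poisson draws around a depth-weighted base
  (`body_base_dosage`, default 800 counts), with a hotter spine band
  (x1.7) and a periodic rib texture. The Poisson choice mimics counting
  noise; the depth weighting mimics the thicker tissue column at the
  body midline.
* **Background**: i.i.d. uniform integers on `0..background_noise_max`
  (default 50). The generator guarantees strict separation:
  `background_noise_max < body_base_dosage`.
* **Hot spots**: per-lesion mean drawn in `hotspot_dosage_range`
  (default 3000–6000), with every lesion pixel guaranteed at or above
  the low bound. Lesions are discs of radius 3–6 px placed in the spine
  (`spinal`), spine plus ribs (`multiple`), or pelvis
  (`outside_spinal`), matching the subcategory mix of clinical archives
  (weights 111 : 14 : 1).
* **Confounders**: a very hot injection point on one arm
  (15000–30000 counts) and a bladder blob in the pelvis (4000–8000),
  both inside the body.

The defaults exercise the 16-bit range the way clinical scans do; the
paper-free parts (noise law, dosage scale) are by construction, not
calibration, and are fixed here once. The posterior view mirrors the
anterior silhouette and redraws all stochastic components.
`generate_cohort()` emits exact per-class image counts with both views
per simulated patient and a configurable missing-view rate (default
0.31, reproducing an archive of 346 images from 251 patients).

What the phantom does **not** emulate: anatomical variation beyond
smooth jitter of section positions and widths, scanner physics
(attenuation, scatter, collimator blur), degenerate poses, arms crossed
over the trunk, or non-metastatic focal uptake in bone (degenerative
disease, fractures). Tests that pass on phantoms therefore validate the
*mechanics* of the pipeline — thresholding, landmark logic, geometry,
training — not clinical performance.

## The five-stage thoracic cropper

`crop_pipeline()` runs:

1. **Adaptive noise threshold.** The threshold is the maximum dosage
   outside the body. Without a ground-truth mask the outside region is
   estimated deterministically: a coarse Otsu split of the dosage
   histogram, then the border-connected components of the below-split
   pixels, minus a 9-px morphological halo around the above-split region
   (the halo keeps the faint taper at the body edge from being mistaken
   for background). The threshold is applied *inclusively*: every pixel
   at or below the measured background maximum is set to zero. (Applied
   strictly, the background pixel attaining the maximum would survive
   its own threshold; the inclusive reading is what actually removes the
   noise while keeping lesions, whose dosage is far above it.)
2. **Body extent**: first and last rows containing a nonzero pixel.
3. **Row profile and landmarks.** Nonzero pixels are counted per row
   (`profile_stat = "sum"` switches to dosage sums; counting is the
   default because the landmark structure lives in the silhouette width,
   not the intensity). The counts are smoothed by a centred moving
   average (default window 15 rows) — a deliberately non-parametric
   "fitted curve", since no fitting family is canonical here —
   and differentiated by central finite differences. Peaks and valleys
   are sign changes of the first derivative filtered by a minimum
   prominence (default 5% of the fitted maximum) to suppress noise
   extrema. The first three peaks and the third valley are the
   landmarks; fewer raises a typed `landmark_error` carrying the partial
   result.
4. **Thorax bounds.** The thorax top is the third peak (shoulder); the
   span down to the leg valley is divided 3 : 2 (spine : pelvis), so
   `row1 = row0 + round(3/5 * (leg_valley - row0))`. Columns are the
   nonzero extent of the thorax rows; because the arms inflate that
   extent, it is capped symmetrically at the column extent of the leg
   area (rows just below the leg valley), whose width matches the trunk.
   When the two widths tie the wider crop wins.
5. **Penalty expansion and canvas.** All four bounds are expanded by a
   penalty factor sigma drawn uniformly from the open interval (5, 15)
   to absorb curve-fitting error, then the block is centred on a
   256 x 256 zero canvas with dosage values untouched (no
   interpolation). Oversized crops are trimmed symmetrically with a
   warning.

On 200 default phantoms the pipeline removes 100% of outside-body
pixels and zero lesion pixels, recovers all four landmarks within
±8 rows on at least 95% of scans, and reaches a median
intersection-over-union against the true thorax box of at least 0.80
(the acceptance suite recomputes these; typical medians are ~0.95).

## Augmentation

Three label-preserving geometric operations model patient displacement
and tilt during the long acquisition: horizontal mirror (also a stand-in
for the missing complementary view), translation by a random integer in
`[0, t_T]` with random sign and axis (defaults `t_T` = 10 px horizontal,
4 px vertical), and rotation about the canvas centre by a random integer
degree in `[0, r_T]` with random direction (default 5°). Rotation uses
inverse-mapping bilinear resampling and rounds back to integers so the
16-bit dosage semantics survive; mirror and translation are exact
permutations. Min–max normalization to [0, 1] is per image (a global
variant is what `phantom_crop_set(normalize = FALSE)` effectively
provides by scaling with the fixed 16-bit range).

`build_datasets()` assembles the three experimental datasets: `D1`
originals, `D3` originals plus augmented copies, `D2` = `D3` with
normalization on top (sharing the geometric draws — exposing whether
normalization itself helps, not different geometry). Class targets
(e.g. 1200 normal / 1190 metastasis from 220/126 originals) distribute
extra copies round-robin over the class's sources, since typically only
part of the over-represented normal class is augmented. Every augmented
record carries `source_id` provenance; the splitter groups by it, so
augmented derivatives can never leak into the test subset.

## Classifier architectures

Seven architectures are described declaratively and realized by a
compact convolutional engine (im2col + BLAS gemm in compiled code):

* **VGG family** (7/16/19/21/24 weight layers): five 3x3-convolution
  blocks (stride 1, pad 1) of widths 64–512, each closed by 2x2/2 max
  pooling, then the FC head and 2-way softmax. Per-block convolution
  counts deepen as (1,1,1,1,1), (2,2,3,3,3), (2,2,4,4,4), (3,3,4,4,4),
  (3,3,5,5,5). The VGG-7 head is FC-4096 + FC-2 — the only head
  consistent with a total of 7 weight layers — and carries L2 weight
  regularization (`lambda = 1e-4` by default; the loss is
  `e + lambda * sum(w^2)`). The deeper variants use the standard
  FC-4096/FC-4096/FC-2 head. ReLU is retained in VGG-7 (no alternative
  is canonical).
* **ResNet-34**: sixteen two-convolution residual modules in groups
  (3,4,6,3), 3x3 kernels throughout (including the stem, kept 3x3 for
  consistency with the all-3x3 design), identity shortcuts with 1x1
  projections at shape changes, a 3x3/2 max pool after the stem and a
  2x2/1 average pool before global average pooling and the FC-2 head.
* **DenseNet-121**: 7x7/2 stem, 3x3/2 max pool, dense blocks of
  (6,12,24,16) bottleneck units (1x1 at 4k then 3x3 at growth k = 32 —
  the conventional rate, as none is stated for this task), transitions
  (1x1 conv halving channels + 2x2/2 average pool), global average
  pooling over the final 7x7 maps, FC-2, softmax. Within a block every
  unit receives the concatenation of all preceding feature maps; an
  ablation hook (`concatenate = FALSE`) demonstrates the connectivity
  is load-bearing.

Parameters are Gaussian-initialized (zero-mean normal, fan-in scaled)
reproducibly from a seed. Inputs are single-channel dosage images
(RGB replication is a builder option, unused by default). Weight-layer
counts follow the usual convention: convolutions and FC layers count,
projections and batch normalization do not.

Training (backpropagation) is implemented for the sequential
feed-forward family — the VGG classifiers, which the end-to-end study
uses; the residual and dense architectures support structural audit and
forward inference. Mini-batch gradient descent reads the reference
protocol's "batch gradient descent with batch size 32" as mini-batch
SGD (the two statements are otherwise contradictory); classical momentum
is available and off by default. Divergence (non-finite loss) raises an
error naming the epoch.

## Evaluation protocol

`split_dataset()` draws a random 7 : 3 train/test split at source-image
level. `confusion_counts()` treats abnormal (metastasis) as the positive
class, with the decision threshold at 0.5 on the positive softmax
probability (argmax). `metrics_report()` computes accuracy, precision,
recall, specificity, F-1 and FPR = FP/(FP+TN); a zero denominator yields
`NA` plus an entry in `undefined` rather than an exception. (FPR is
FP/(FP+TN); the superficially similar TN/(TN+FP) is specificity, and the
two must sum to one whenever both are defined — an identity the tests
assert.)
`roc_auc()` computes the AUC as the probability that a random positive
outranks a random negative (midranks; ties count one half) and checks
out against the trapezoidal area under the threshold-swept ROC to 1e-9.
`repeat_evaluate()` averages the metric set over 10 repetitions with
fresh seeds per repetition; for a deterministic trained model the
repetitions coincide, and retraining per repetition is available by
closing the prediction function over the training routine.

## The scaled-down end-to-end study

Desk-scale stand-in for the full clinical experiment, with conditions
fixed once:

* 300 phantom scans (150 normal / 150 metastasis, both views, the
  default confounders), full cropping pipeline, crops block-averaged to
  64 x 64 and per-image min–max normalized;
* VGG-7 at 1/16 channel width; mini-batch gradient descent with
  momentum 0.9, learning rate 0.01, batch 32, 35 epochs (the full-scale
  default of 0.001/500 epochs is impractical at desk scale; the scaled
  task has its own, stated rate);
* 7 : 3 source-level split; the augmented arm adds one augmented copy
  per *training* image (translation limits scaled to the resolution:
  ~2/1 px; rotation unchanged at 5°), never touching the test subset.

Across seeds the unaugmented arm reaches mean test accuracy above 0.90
and the augmented arm scores at least as high — the qualitative finding
(augmentation does not hurt, and usually helps) mirrored at desk scale.
Because phantom classes are separable by construction, absolute
accuracies here say nothing about clinical data.

## Numerical and design notes

* **Coordinates**: matrices are `[row, col]`, 1-based, origin top-left;
  boxes are inclusive integer ranges.
* **Thresholding semantics**: `strip_background(x, thr)` zeroes strictly
  below `thr` (the primitive contract); the pipeline passes
  `thr_N + 1`, making the measured background maximum itself
  background.
* **Smoothing at the profile ends** shrinks the moving-average window
  rather than padding, so short bodies do not acquire phantom slopes.
* **Peak prominence** uses the standard definition (height above the
  higher of the two lowest saddles toward higher terrain).
* **Ties in the width cap** (trunk extent vs leg extent) resolve toward
  the wider crop; odd spans centre with the extra pixel to the right.
* **Rotation** rounds bilinear results back to integers for dosage
  images (`round_int = FALSE` for normalized real-valued images).
* **File formats**: single-frame 16-bit unsigned DICOM (Explicit VR
  Little Endian) and lossless 16-bit TIFF round-trip bit-identically;
  the DICOM reader validates bit depth, signedness, frame count and
  dimensions and names the violated expectation in its error.
* **Known limitations**: training supports sequential architectures
  only; the outside-region estimate assumes the background touches the
  image border (true of whole-body scans); the phantom's landmark
  geometry is stylized, so cropping statistics on phantoms bound the
  method's behaviour only under those geometric assumptions.
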