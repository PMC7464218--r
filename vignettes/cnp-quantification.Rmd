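---
title: "Quantifying retinal capillary non-perfusion: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal capillary non-perfusion: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Capillary non-perfusion (CNP) — retinal territory that has lost capillary
flow — appears on ultra-wide-field fluorescein angiography (UWF-FA) as
hypofluorescent regions of lesser grayscale than the normal "ground-glass"
background, with absent or pruned arterioles. Outlining these regions pixel
by pixel is slow and subjective, and downstream trial endpoints need a
*standardized topography*, not free-form polygons. `cnpquant` implements a
two-stage pipeline: (1) a dense segmentation network produces a per-pixel
CNP probability map; (2) a fovea-centred concentric grid converts any dense
mask — human or automated — into 72 perfused/non-perfused segment labels
that can be compared across graders, models and visits, with the agreement
statistics (Cohen's kappa, ICC, Dice, fold-averaged ROC/PRC) used to
validate such pipelines.

## Stage 1: dense segmentation

### Preprocessing and augmentation

Frames are reduced to the central 2000×2000 px region, resized to 448×448
(bilinear for intensities, nearest-neighbour for masks so they stay
binary), and normalized to mean 0.5 and standard deviation 1.0. We use the
*population* standard deviation over the *full* crop: the convention has to
be fixed for exactness tests, and at 448² the sample/population difference
is far below any meaningful scale.

Training draws one augmentation per step, every random value uniform:

* **Contrast** `mu + gamma * (x - mu)`, `gamma` in [0.8, 1.2].
* **Brightness**: an additive offset, `U(0, 0.1)` times the intensity
  range, with random sign. A literal multiplicative scaling by a factor
  below 0.1 would destroy the image, so the additive reading is the
  default; the multiplicative variant stays available behind
  `brightness_mode = "multiplicative"` for anyone wanting the literal rule.
* **Flips**, horizontal and vertical, each with probability 0.5.
* **Shear + rotation**: shear factors and the rotation angle drawn from
  (−0.25, 0.25), the angle read as radians (≈ ±14°, a plausible
  acquisition-tilt range; no unit that keeps the same numerals produces a
  more physiological warp). Out-of-frame pixels are filled with the image
  mean and marked non-gradable, so the warp invents no gradable content.
* **Random crop** keeping at least 63% of the area with per-axis keep
  ratios whose mutual ratio is at least 0.7, then resize back. The sampler
  draws both axis ratios uniformly on [0.63, 1] and rejects pairs violating
  either bound; the crop sides are rounded *up* so the realized pixel area
  never dips below the sampled one.

Masks undergo exactly the geometric transforms and none of the photometric
ones, which preserves the containment invariant (CNP ⊆ gradable) exactly
under nearest-neighbour warping.

### Network

`build_network()` constructs the standard symmetric encoder–decoder:
`depth` encoder blocks of two 3×3 convolutions (ReLU) followed by 2×2 max
pooling with stride 2, channel counts doubling from `base_channels`; a
bridge of two 3×3 convolutions with dropout (rate 0.5, the only dropout
site, active only in training); `depth` decoder blocks that upsample ×2,
concatenate the matching encoder feature map, and apply two 3×3
convolutions; and a final 1×1 convolution from the last
`base_channels`-channel map to the class scores, softmaxed per pixel. All
convolutions use "same" zero padding so the output probability map has the
input's spatial shape — a requirement for overlaying the grading grid on
full frames. Upsampling is bilinear interpolation (no transposed
convolution): it is parameter-free, artifact-free, and the following 3×3
convolutions supply the learnable mixing. Weights are He-uniform, biases
zero.

The forward/backward passes are implemented in the package (R orchestration
over a small Armadillo kernel for the convolution, pooling and upsampling
operators and their adjoints); the gradient of every operator is verified
against finite differences in the test suite.

### Objective

The training loss is the inverse generalized Dice overlap

$$\mathrm{GDL} = 1 - 2\,
  \frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
       {\sum_l w_l \sum_n (r_{ln} + p_{ln})},
\qquad w_l = \Big(\sum_n r_{ln}\Big)^{-2},$$

with classes `l` ∈ {CNP, background}. The inverse-squared-size weights stop
the large background class from swamping the CNP class. When a class is
absent from the reference, its weight is undefined (0⁻²); we replace it by
the largest finite weight in the batch, which keeps the loss finite and
bounded in [0, 1] and reduces to plain Dice behaviour on the remaining
class. By default the sums run over all pixels; `loss_region =
"gradable_only"` restricts them to the gradable retina. Either convention
is defensible; all-pixels is the default here because the periphery then
explicitly trains as background rather than being invisible to the loss.

### Optimization

SGD with momentum 0.9, batch size 1, initial learning rate 0.05 decaying by
0.9 every 1000 steps. "Epochs" at batch size 1 are read as optimizer steps:
33,000 dataset passes over 60 training images would be two million updates,
while 33,000 single-image steps (~550 passes) is the natural reading and is
the package default (`train_config()`).

**Desk scale.** The test suite and the acceptance script run a reduced
configuration — 128 px inputs, depth 3, 16 base channels, 300 steps, 10–12
synthetic images — chosen so a full three-seed training experiment finishes
in minutes on one CPU core. At this scale the full-scale learning rate
0.05 is unstable: within ten steps a momentum-amplified gradient spike
saturates the softmax and the network dies (divergence observed for
lr ≥ 0.02, and at 0.005 an occasional initialization still collapses
mid-run the same way). Desk-scale runs therefore use `lr0 = 0.002`, which
trains stably across initializations, and enable only the
cheap augmentations (flips, contrast/brightness); the warp and crop paths
are exercised by their own property tests. The full-scale defaults in
`train_config()` are unchanged.

## Stage 2: the concentric grading grid

The template is a central circle of 1 disc diameter (DD) centred on the
fovea — the foveal avascular zone, excluded from grading — surrounded by 6
rings whose outer radii grow by 2.5 DD per ring, each divided into 12
segments of 30°, i.e. 72 gradable segments out to 15 DD. Fovea position and
the pixels-per-DD scale are *calibration inputs* (from the manifest);
automatic fovea or disc detection is out of scope. The abstract-level
distinction between "centred on the FAZ" and "centred on the fovea" is
treated as the same calibrated point.

Automated labelling of a segment:

* `gradable_fraction` = gradable pixels / in-image pixels. Below 0.5 the
  segment is **U** (ungradable). This mirrors the ">50% of the segment"
  majority rule human graders apply; the cutoff is a parameter.
* otherwise `cnp_ratio` = CNP pixels / *gradable* pixels in the segment,
  and the segment is **N** exactly when the ratio strictly surpasses the
  threshold (default 0.30; 0.40 and 0.50 are the other studied values),
  else **P**. Using gradable pixels as the denominator follows from CNP
  being defined only within the gradable retina; an all-pixel denominator
  would bias peripheral, partly-covered segments toward P.

Pixels belong to segments by a pixel-centre point-in-region test — no
partial membership — so all counts are integers and the tie rule is exact.
Segment 1 starts at 12 o'clock and numbering runs clockwise, 1-based
(ring, segment); the orientation is configurable and only a labelling
convention.

## Agreement statistics

* **Pixel level**: precision TP/(TP+FP), recall TP/(TP+FN), Dice
  2TP/(2TP+FP+FN), always computed within the reference gradable region.
  An empty denominator yields a missing value, never 0.
* **ROC/PRC**: pixels are pooled across a fold's images within the
  gradable region, the threshold swept over a uniform grid, areas obtained
  by trapezoidal integration along the sweep (with the conventional
  recall-0/precision-1 anchor for the PR curve). Fold curves are averaged
  vertically on a common 101-point grid; we report both the area of the
  mean curve and mean ± sd of per-fold areas.
* **Kappa**: unweighted Cohen's kappa per image over segments gradable in
  both assessments, then mean and standard error over images. Two identical
  constant label vectors have chance agreement 1 and the formula becomes
  0/0; observed agreement is perfect there, so kappa is defined as 1 —
  mostly-perfused retinas otherwise register as disagreement.
* **ICC**: two-way random effects, absolute agreement, single measurement —
  ICC(2,1) — on per-image counts of perfused (and of non-perfused)
  segments, with the F-based 95% CI. Absolute agreement matches the intent
  of comparing raters' actual counts, not their rank orders. Zero variance
  in both raters leaves the coefficient undefined (missing), except that
  identical vectors *with* variance give exactly 1.

## The synthetic-data generator

No public UWF-FA dataset with CNP masks exists, so every stage is validated
on seeded synthetic frames (`synthetic_spec()` / `generate_image()`) that
emulate the features the method actually exploits:

* band-limited value noise for the ground-glass background texture;
* an elliptical gradable region (vertical compression 0.8 by default,
  reflecting lash artifacts) with exponential peripheral falloff and a few
  bright peripheral artifacts;
* hypofluorescent CNP patches: wobbled-border ellipses sized to split a
  target fraction (default 0.28 of the gradable area, matching reported
  grader burdens of roughly 26–28%) with per-patch darkening factors of
  0.35–0.75 ("mild loss of greyness to complete hypofluorescence");
* a recursive branching vessel tree of bright anti-aliased curvilinear
  segments radiating from a disc placed 2.5 DD from the fovea, erased
  inside CNP patches so vessels end abruptly — pruned — at patch borders;
* additive Gaussian sensor noise; a foveal intensity dip; 16-bit output.

Patch placement is random and clipped to the gradable ellipse, so the
achieved CNP fraction is controlled only to about ±20% relative tolerance —
exact fractions are not enforced, matching the generator's contract.
`simulate_second_grader()` emulates inter-grader variability: random patch
additions/deletions followed by growth or shrinkage along the distance
transform until the area matches `original × (1 + bias)`. This reproduces,
qualitatively, the reported pattern of a second grader annotating ~40% more
CNP area: agreement with the reference falls monotonically as the bias
grows.

What the generator does *not* emulate: dye-transit dynamics, leakage and
staining, microaneurysms, eyelash shadows with structured geometry,
camera-model illumination fields, or inter-eye anatomical variability.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that the statistics behave as designed on a separable task —
not that the trained network reaches any particular accuracy on clinical
images.

## Numerical choices and degenerate inputs

* Normalization rejects constant images (zero standard deviation).
* `binarize()` uses a strict `>`, so probabilities exactly at the threshold
  stay background; segment labelling likewise uses strict "surpassed".
* Empty or off-image grid segments are labelled U, never an error.
* Kappa with fewer than two jointly gradable segments is missing; missing
  per-image kappas are excluded from the dataset mean and its n.
* Model checkpoints serialize to JSON at full printed precision;
  round-trips agree to ~1e-14 relative, far below training noise.
* All randomness flows through explicit integer seeds
  (generator specs, weight init, training, augmentation, fold splits), and
  every seeded operation restores the caller's RNG state.

## Problem sizes used by the checks

Synthetic fixtures are 512 px (the generator's minimum) with 16 px/DD so
the full 15-DD grid fits the frame; the training experiments use 10
training and 2 held-out images at 128-px input; cross-validation smoke runs
use 2 folds at reduced step counts. These sizes were chosen as the smallest
at which the separability, agreement and convergence properties are
comfortably observable.
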