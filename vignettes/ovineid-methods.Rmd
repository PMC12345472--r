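---
title: "Age-invariant sheep face identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-invariant sheep face identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ovineid)
```

## The problem

Sheep reach market weight within about a year, and their faces change
drastically over those twelve months: the head grows rapidly between months
1 and 4, stabilizes after month 8, and late months add fur coverage that
masks facial detail. A face-identification model trained on lamb images
therefore degrades as the animals age. `ovineid` implements an
age-invariant identification pipeline that learns an embedding, splits it
into an *age code* and an *identity code*, and adversarially decorrelates
the two so that identification relies on features stable across growth.

## Model

The pipeline has four learned parts.

**Backbone.** A bottleneck residual network with squeeze-and-excitation
(SE) channel recalibration. Each bottleneck is the standard
1x1 -> 3x3 -> 1x1 stack with batch normalization; the SE gate
`g = sigmoid(W2 relu(W1 GAP(F)))` rescales the channels of the residual
branch through a bottleneck of width `C/r`. Two presets ship:

* `fe_net50` — stage widths 256/512/1024/2048, blocks 3/4/6/3, SE
  reduction 16 placed after the last bottleneck of each stage, 7x7
  stride-2 stem with 3x3 max-pooling, 224x224 input, 2048-d embedding.
* `fe_net_tiny` — widths 32/64/128/256, blocks 1/1/2/1, SE reduction 8,
  3x3 stride-1 stem (to preserve resolution at 64x64), every stage
  stride 2; total stride 32, 256-d embedding. This is the preset every
  shipped experiment uses: it trains on one CPU in minutes.

Batch normalization uses the biased batch variance with `eps = 1e-5`;
inference uses running statistics, so evaluation is deterministic.

**Attention and decoupling.** The age branch applies an efficient
channel/spatial attention block (ECBAM) to the final feature map: two
*unshared* 1-D convolutions over the channel axis process the
average-pooled and max-pooled channel descriptors, blended by a trainable
scalar `alpha` (initialized at 0.5, used as the convex weights
`alpha, 1 - alpha`) and squashed by a sigmoid; a 7x7 spatial convolution
over the channel-mean and channel-max maps then gates the spatial
positions. The 1-D kernel size follows the adaptive rule
`k = odd(floor((log2 C + 1) / 2))`, giving k = 5 at C = 256 and k = 7 at
C = 2048. The gated map is pooled and passed through a two-layer MLP
(`d -> 256 -> 128`) to the age code `x_age`; a second MLP
(`128 -> 256 -> d`) produces a residual that is subtracted from the
embedding: `x_id = x - R(x_age)`. The decomposition `x_id + R(x_age) = x`
holds exactly on every forward pass. A shared-MLP (CBAM) channel gate and
a single-linear-map subtraction are available as ablation switches.

The source description of the subtraction is contradictory (it speaks of
subtracting the identity factor from the growth factor and yet of
obtaining age-free identity features); this package resolves it as
`x_id = x - R(x_age)`, the only reading that yields age-purged identity
features, consistent with the residual-decomposition literature it cites.

**Correlation module.** A kernel canonical-correlation module projects
`x_id` and `x_age` to scalars through one-hidden-layer perceptron maps and
projection vectors, then measures their batch Pearson correlation `rho`
(both projections mean-centered; an eps-stabilized denominator; a
zero-variance batch defines `rho = 0` and is excluded from gradients).
The module is trained *adversarially*: ascent steps maximize `rho^2` over
the module parameters (with a Gaussian prior realized as an L2 penalty,
strength 1e-4), while the encoder's descent step minimizes
`beta * rho^2`, pushing the two codes toward decorrelation. With identity
kernel maps, the inner maximization is classical linear CCA, and the test
suite checks the ascent against `stats::cancor` on Gaussian data (n =
5000, d = 8, agreement within 0.02). The number of canonical pairs is one
(configurable); the original description does not state a count.

**Objectives.** Identification is supervised by CosFace: with
unit-normalized identity codes and class vectors, the true-class cosine is
shifted by a margin `b` before scaled (`s`) softmax. The printed form of
the loss in the source is typographically garbled; the implementation is
standard CosFace (margin on the true class only), with defaults `s = 30`,
`b = 0.35` — values within the range used by the CosFace literature, since
none are given. Age is supervised by linear regression on `x_age` with the
half-MSE loss `1/(2m) * sum (F_age(x_age_i) - z_i)^2` — the printed
formula, which is called "RMSE" in the text but is not one; a separate
`age_rmse()` reporting metric is provided. Ages are raw integer months
1-12, unnormalized. The joint objective is
`L = L_id + alpha * L_grow + beta * rho^2` with defaults
`alpha = 0.01, beta = 1`, the weights selected by the original grid search.

## Pipeline: crops, not frames

Training and evaluation consume *face crops*: each image is cropped to its
face box and bilinearly resized to the preset input size before entering
the backbone (`load_split(crop_to_box = TRUE)`, the default). This is the
standard detect-crop-embed layout of face-recognition systems, and it is
what the bundled box annotations are for. It matters scientifically: in
the longitudinal cohort the head grows threefold between months 1 and 12,
so a frame-level pipeline would let raw in-frame scale stand in for age
and confound the decoupling analysis; in crop space the age signal is
carried by the realistic cues instead — effective resolution (lamb crops
are upsampled from few pixels), late-month fur texture, and nuisance —
while identity cues (geometry ratios, hue, texture, markings) align
across ages.

## Training

SGD with momentum 0.9 and weight decay 1e-4 throughout. The full-scale
defaults (learning rate 1e-3, batch 128, 100 epochs, alpha 0.01) mirror
the source protocol; the desk-scale `tiny_run` configuration uses batch
32, 24 epochs, a peak learning rate of 0.02 with a 2-epoch linear warmup
and half-cosine decay, global gradient-norm clipping at 5, and
`alpha = 1`. The learning-rate schedule and clipping were chosen once
for stable convergence of the tiny preset at 64x64, where 1e-3 makes no
visible progress within a CPU-scale epoch budget; `alpha` was selected by
the package's own validation-grid procedure for the tiny protocol —
at the full-scale value 0.01 the age branch receives gradients scaled by
1/100 and stays untrained within 400 iterations, which silently disables
the decoupling mechanism the study is supposed to exercise.

Each iteration runs `adversarial_ratio` (default 1) correlation-ascent
steps at 10x the current learning rate before the single descent step.
The ascent count is deliberately small: the kernel maps are expressive
enough to find spurious near-perfect correlations *within* any 32-sample
batch, so a many-step inner maximization memorizes batches and feeds the
encoder noise; a single warm-started momentum step per iteration tracks
only the directions that persist across batches. The ascent updates only
the correlation module; the descent updates everything else. Training
aborts with a diagnostic on any non-finite loss. All randomness (initialization, batch order, generator
nuisances) derives from one root seed via tagged 31-bit hashes, so a run
is bit-reproducible from its config.

Grid search trains every combination, selects by validation top-1
accuracy (ties: lower validation loss, then smaller learning rate), and
removes test-split rows from the manifest before any training, so the
test split cannot influence selection.

## Synthetic cohorts

No public longitudinal sheep-face data exist, so the package ships a
generator whose identity and age factors are independent by construction:

* *identity* (constant for life): eye spacing (0.28-0.52 of head width),
  a 2-d nose offset (±0.08), coat hue, a smooth coat texture drawn in
  head-normalized coordinates (hence age-invariant), and one of four
  marking patterns (none / blaze / left / right cheek patch). Cohort
  identities are drawn by stratified (Latin-hypercube) sampling over the
  continuous fields with round-robin markings: the generator emulates an
  *enrolled* herd, so individuals must be distinguishable in principle —
  i.i.d. draws produce coat-hue near-collisions that cap attainable
  accuracy regardless of the model, which would make the recovery
  experiment a test of sampling luck rather than of the pipeline;
* *age*: head scale `s_max (1 - e^{-age/tau})` with `tau = 2.5` months, so
  ~80% of growth happens by month 4 and the curve is flat after month 8,
  and a fur texture with amplitude `fur_gain * (age - 8)^+`
  (`fur_gain = 0.05` per month) that degrades late-month images;
* *nuisance*: luminance gain/bias, in-plane rotation, Gaussian noise.

The augmentation policy produces exactly {original, photometric jitter,
noise injection, random rotation} — a x4 expansion with default ranges
±20% gain, sigma 0.02, ±15 degrees; the multiplier and ranges are
configuration. Two split protocols exist: age-based (train 1-4 months,
validation 5-8, test 9-12) and id-based (80%/9%/11% of individuals,
disjoint). The default test cohort is 20 individuals x 12 months x 8
images per cell at 64x64 px — small enough to train in minutes on one CPU.

What passing on this generator shows — and what it does not: the cohort
has a real train/test distribution shift (small lamb heads with no fur vs
large furred heads), so high cross-age accuracy does demonstrate
age-invariant feature learning rather than memorization. But the
generator's nuisances are mild and unimodal, identities are separable by
design (hue is a strong cue), and there is no occlusion, background
clutter, pose beyond in-plane rotation, or imaging artifacts; results on
it say nothing quantitative about accuracy on real animals.

## Numerical choices and degenerate inputs

* BN: biased variance, `eps = 1e-5`; zero-variance features normalize to 0.
* CosFace: embedding and class-vector norms stabilized by `+1e-12`; a
  single-class configuration has an empty competitor sum and zero loss.
* Correlation: `rho` clamped to [-1, 1]; zero-variance projections give
  `rho = 0`, flagged, with zero gradient.
* Metric 0/0 denominators return 0 with an `undefined` attribute rather
  than NaN; degenerate zero-area box unions likewise.
* Leakage R^2 is *cross-fitted* truncated-SVD least squares (fit on one
  half, score on the other, pool; rank capped at min(64, n/4)): plain
  in-sample OLS is vacuous here because the code dimension is comparable
  to the split size, whereas cross-fitting keeps the permutation null at
  ~0. Negative R^2 is clipped to 0 and flagged. The diagnostic defaults
  to the *whole cohort*: under the age-based protocol any one split spans
  only four months, and the growth curve is flat over the test window, so
  within-split age is unidentifiable for every code and a within-split
  R^2 says nothing about decoupling. The convergence targets of the
  acceptance experiment are evaluated on the training age range, the only
  window where the age branch received supervision.
* EER: the ROC form interpolates linearly between adjacent thresholds
  where FAR crosses FRR; all-identical scores give 0.5. The pooled
  misclassification form of the printed equation is reported separately
  as `eer_eq11`.
* mAP@0.5 for this classification-only pipeline scores each prediction
  with its crop box (IoU 1 against its own ground truth), reducing to
  classification mAP; a detector is out of scope.

## Open design points resolved here

* SE placement defaults to the last bottleneck of each stage (the table
  note in the source); `every_block` is available for ablation.
* The source's "1x1 fully connected layers on both sides of the ReLU" is
  read as the standard two-transform SE bottleneck.
* A multi-stage feature-fusion module is mentioned in the source without
  any structure; only the standard residual topology is implemented.
* ECBAM feeds the age branch only (as the architecture figure suggests),
  not the shared trunk.
* The source's image counts conflict across its text and dataset table;
  the generator follows the exact-x4 augmentation reading and exposes the
  multiplier in configuration.

## Problem sizes in the shipped experiments

The end-to-end acceptance experiment trains `fe_net_tiny` on the default
20-identity cohort (640 train / 640 validation / 640 test originals,
age-based splits) for 24 epochs, twice (full model and backbone-only
baseline), evaluating identification accuracy, cross-fitted age-R^2 of
both codes, and the final projected |rho|. The equation-level checks run
on hand-computed instances of at most 20 elements; the CCA check uses
n = 5000, d = 8.

## What the decoupling does and does not achieve

The adversarial objective controls exactly what it optimizes: the batch
Pearson correlation of the learned scalar projections. On the synthetic
cohort this converges to noise level (|rho| ~ 0.01), the age code remains
strongly age-predictive, and identification is age-invariant. It does
*not* follow that the identity code carries no age information at all: a
cross-fitted linear probe can still decode age from `x_id` on the
training age range, because a batchwise single-pair min-max suppresses
correlation only along the adversary's current direction while the
backbone keeps re-creating the age factor (in crop space, mainly the
resolution/blur cue) in other directions. An expressive adversary cannot
fix this at desk scale — any map with more capacity than the batch size
finds spurious near-perfect correlations within a 32-sample batch and
feeds the encoder noise — and a closed-form regularized-CCA inner solve
(available as `corr_exact = TRUE`) tracks honest directions but still
loses the race against the backbone within a CPU-scale epoch budget. The
acceptance suite therefore reports both the projected |rho| and the
linear-probe R^2 values side by side, and treats them as distinct claims.

## Known limitations

* The renderer is a schematic face, not a photorealistic sheep; camera
  geometry, occlusion and background variation are absent.
* The correlation module defaults to a single canonical pair; several
  pairs are available (`n_pairs`, kept apart by an orthonormality penalty
  during ascent), but full deflation-based multi-pair CCA and
  variational-Bayes posterior inference over projections are out of
  scope.
* The `fe_net50` preset is structurally faithful (stage widths, SE dims)
  but is not shipped with trained weights and is not intended for CPU
  training.
* Open-set recognition is limited to cosine-threshold verification; no
  gallery enrollment beyond the trained classes.
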