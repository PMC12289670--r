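---
title: "Growth-stage detection and RGB-D localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-stage detection and RGB-D localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strawyolo` is a toolkit for detecting the four growth stages of strawberry
— bud, flower, under-ripe fruit, ripe fruit — in orchard RGB images, and for
placing each detection in camera-frame 3D coordinates using an aligned depth
map. This vignette records the models it implements, the design decisions
that were genuinely open, and what the synthetic test bed does and does not
demonstrate.

## The detector

The base network is a YOLOv8-family single-stage anchor-free detector: a
CSP-style backbone (stem, staged cross-stage `C2f` blocks, a spatial-pyramid
fast-pooling tail), a path-aggregation neck merging three pyramid levels
(strides 8, 16, 32), and a decoupled head that predicts per-cell class
scores and a discrete distribution over box-side distances (16 bins per
side, decoded by the softmax expectation). Compound scaling presets follow
the usual depth/width multiples: scale `n` is (0.33, 0.25) and scale `s`
(0.33, 0.50).

Two attention blocks extend the baseline:

**SE-MSDWA** (squeeze-and-excitation enhanced multi-scale depthwise
attention) sits at the deep end of the backbone. A 5×5 depthwise convolution
extracts local spatial structure; three depthwise strip-kernel pairs —
(1,5)+(5,1), (1,9)+(9,1), (1,17)+(17,1) — add small, medium and large
receptive fields at depthwise cost; their sum passes through a pointwise
1×1 fusion convolution and a squeeze-and-excitation stage (global average
pool, two fully connected layers, sigmoid) that reweights channels. The
resulting attention map `a` is applied to the block input as
`x * a + x`. Because the multiply/residual wiring is parameter-free, it
cannot be pinned down by parameter accounting; this form was chosen for
optimization stability (the block can always fall back to identity).

**CGFM** (context-guided fusion module) replaces each of the four channel
concatenation nodes in the neck. The two incoming maps are spliced, passed
through a 1×1 convolution and multi-head self-attention over spatial tokens
(stride-2 token subsampling for maps larger than 20×20, restored by
nearest-neighbor upsampling; this is parameter-neutral and bounds the
quadratic token cost). The sigmoid of the attention output is split into
two channel-wise gates; each input is gated and blended with a 1×1
channel-matched projection of the other input, and the two blended maps are
re-concatenated. Output channels equal the sum of the input channels, so
the module is a drop-in replacement for concatenation and leaves all
downstream widths untouched.

## Parameter accounting

Every layer has a closed-form parameter count, and `count_parameters()`
enumerates the learnable arrays of a built model; the two are tested for
exact agreement on randomized configurations. Model sizes are reported in
millions **truncated** to two decimals (`params_millions()`), because that
is the convention under which the baseline sizes print as 11.16 M (scale s;
11,166,544 trainable scalars) and 3.15 M (scale n; 3,157,184) — rounding
would print 11.17 and 3.16. The head's distribution-expectation projection
is a fixed arithmetic operation with no learnable scalars.

Three hyperparameters of the attention blocks are not determined by their
published description and were calibrated once against the published model
sizes, then frozen:

- SE-MSDWA is inserted twice — after the pyramid-pooling tail (512
  channels at scale s) and at the end of the next-deepest backbone stage
  (256 channels). A single insertion cannot reach the published size gap
  for any integer squeeze-and-excitation reduction ratio, so the
  two-insertion layout is the one the parameter budget selects.
- Its reduction ratio is 4, its convolutions carry no biases (the
  squeeze-and-excitation layers do), and there is no batch normalization
  inside the block.
- The CGFM attention embedding widths are 628 (768-channel nodes) and 316
  (384-channel nodes), about 0.82 of the spliced width, rounded to a
  multiple of the 4 heads.

With these settings the full modified detector at scale s with the standard
80-class head has 18,697,520 trainable parameters (18.69 M), the
SE-MSDWA-only variant 11.72 M, and the CGFM-only variant 18.13 M. The last
figure is 0.03 M above its published counterpart; the published per-variant
deltas (0.56 and 6.94 M) are arithmetically inconsistent with the published
total delta (7.53 M) under any additive block configuration, so the
calibration prioritizes the baseline and full-model sizes and accepts the
small discrepancy on the intermediate ablation.

## Warmup-scheduled augmentation

Augmentation probabilities ramp with the epoch: `N = current_epoch * 5 /
total_epochs`, `P = min(N, 1)`, and every augmentation's base probability is
multiplied by `P`. Epochs are 0-based, so the first epoch trains on clean
images, and `P` reaches exactly 1 at one fifth of training. The scalar `P`
gates probabilities rather than magnitudes — the schedule controls *whether*
an augmentation fires, matching the idea of easing the model into the data
distribution. The base pipeline (mosaic, translate/scale affine, HSV jitter,
horizontal flip) mirrors the baseline detector's defaults and is config
driven; mosaic is not disabled in the final epochs by default, since the
warmup idea as adopted here only shapes the start of training.

## Training

The loss is the baseline-standard composite: binary cross-entropy on class
scores against task-aligned soft targets, complete-IoU loss on decoded
boxes, and distribution focal loss on the two bins bracketing each true
side distance, with gains 7.5 / 0.5 / 1.5 and normalization by the summed
target scores. Assignment is task-aligned: candidate anchors whose centers
lie inside a truth are ranked by `score^0.5 * IoU^6`, the top 10 are
selected, conflicts resolve to the higher-IoU truth, and target scores are
normalized per truth to its best IoU. The optimizer is Adam at an initial
learning rate of 0.01 under cosine annealing to 1% over the configured
epochs (default 100, batch 32, image size 640), with global gradient-norm
clipping at 10 as a safeguard.

The network, its gradients and the optimizer are implemented natively:
RcppArmadillo im2col/BLAS kernels for convolution and pooling, and a
tape-based reverse-mode autodiff for everything else. Every primitive's
gradient is finite-difference checked in the test suite.

Two initialization choices matter at small problem sizes:

- The classification head biases start at `log(5 / nc / (640/stride)^2)`,
  the standard prior-probability initialization.
- The distribution-head biases decrease across bins (4, 2, 0, …), so a
  freshly initialized model predicts box sides of about 1.7 grid units.
  With uniform bin biases the initial boxes are implausibly large, their
  IoU with small objects is near zero, and the task-aligned targets
  collapse toward zero before learning can start — an interaction that only
  becomes visible on short schedules.

Batch-norm running statistics are recalibrated after training (and before
each validation pass) by averaging batch statistics over up to 16 clean
training batches. On short schedules the momentum-based running estimates
(momentum 0.03) lag hundreds of steps behind the trained weights, which
makes inference-mode behavior diverge badly from training-mode behavior;
the recalibration pass removes that lag at the cost of one forward sweep.

## Synthetic scenes

The scene generator emulates the study conditions the detector is meant
for: 640×640 images, four growth-stage classes drawn as parametric colored
shapes (pale lobed cluster = bud; white petals around a green core =
flower; green-to-red gradient disc = under-ripe; red speckled disc = ripe)
on a leaf-green cluttered background, placed at camera distances of
30–80 cm with physical radii of 1.2–2.6 cm, projected through a pinhole
camera (600 px focal length at 640 px image width, scaled with image size).
Depth maps carry each object's depth in millimeters with nearest-object
occlusion; labels are the exact projected boxes; datasets are split 7:2:1
by a seeded shuffle. One constraint is imposed on top of the stated ranges:
every object must subtend at least 8 px at the configured render size, the
assignability limit of the stride-8 anchor grid. At the native 640 px scale
this floor never binds; it only lifts radii in heavily downscaled fixtures.

What passing tests on these scenes show: the training loop optimizes, the
metric code ranks and integrates correctly, geometry round-trips, and the
architecture wiring is sound. What they do not show: performance on real
orchard imagery — the shapes are trivially separable by color and texture
compared to real strawberries under occlusion and variable light, and no
photometric camera model (noise, blur, exposure) is simulated.

## Evaluation and localization conventions

Average precision integrates the monotone precision envelope at 101 recall
points (the de-facto COCO convention); the test suite bounds the
discretization error against an exact step-integration oracle at every IoU
threshold. Matching is class-wise greedy in confidence order; 0/0 ratios
are defined as 0; classes without ground truths are excluded from the mean
with a warning. mAP@0.5:0.95 averages over IoU thresholds 0.50–0.95 in
steps of 0.05. Non-maximum suppression is class-wise greedy (defaults:
confidence 0.25, IoU 0.7) and is tested against a brute-force suppressor.

A detection's depth is the median of valid (nonzero) depth pixels in the
central 20%-by-area crop of its box — the center crop avoids background
pixels at the box edges, the median resists outliers. Back-projection is
the pinhole model `X = (u - cx) Z / fx`, `Y = (v - cy) Z / fy`, with depth
stored in millimeters and converted by `depth_scale = 0.1` to centimeters.
The reported distance is the Euclidean norm of `(X, Y, Z)` by default;
whether a printed camera distance is Euclidean or raw depth is ambiguous in
common usage, so a raw-`Z` mode is provided.

## Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to exercise every code path
in a desk-scale run: parameter targets on the full-size architectures
(construction only); metric and NMS oracles on 20-image / 50-box problems;
localization round-trips on single-object noiseless scenes; and an overfit
smoke test that trains the scale-n detector on the 32-image training split
of a 46-scene 96×96 dataset for 30 epochs at batch 2 with augmentation
disabled (the small batch trades batch-norm stability for more optimizer
steps, which matters most on a 30-epoch schedule). The smoke test is a memorization check of the optimizer and loss
path — augmentation would measure generalization, which is not its purpose
and is covered by the augmentation module's own distributional tests.
Training-set mAP@0.5 of at least 0.9 is the passing bar.

## Known limitations

- No pretrained weights and no transfer learning: every run starts from
  random initialization, so real-data performance claims are out of scope.
- CPU-only, double precision; throughput is far below GPU deep-learning
  frameworks, which bounds practical training to small studies.
- The multi-head attention order in CGFM (attend, then split into gates)
  follows the block's data-flow description; an alternative reading (split
  before attending) exists but is inconsistent with the gating step.
- Mosaic augmentation requires a pool of donor images and is skipped when
  fewer than three are available.
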