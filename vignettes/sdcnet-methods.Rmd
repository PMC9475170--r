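---
title: "Segmenting thyroid nodules in ultrasound with an N-shape dilated-convolution network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting thyroid nodules in ultrasound with an N-shape dilated-convolution network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcnet)
```

## The problem

B-mode ultrasound is the first-line imaging modality for thyroid nodules.
Nodules that matter clinically are typically *hypoechoic* (darker than the
surrounding parenchyma) with blurred, irregular margins, and the images are
corrupted by multiplicative speckle — granular interference noise intrinsic
to coherent imaging. Delineating the nodule boundary is the step on which
downstream shape-based malignancy features (taller-than-wide, spiculation)
depend, and it is exactly the step that low contrast and speckle make hard.

`sdcnet` implements a U-shaped fully convolutional encoder–decoder for this
binary segmentation task, extended by three components:

1. a **multi-scale input layer** that turns the image into a pyramid by
   repeated 2×2 average pooling and injects each scaled image into the
   matching encoder level;
2. an **attention guidance module** that gates each encoder feature map by
   a one-channel sigmoid mask computed from the scaled input image and the
   feature map, placed *before* every skip connection;
3. a **stackable dilated convolution (SDC) block** in the bottleneck:
   four parallel cascades of 3×3 dilated convolutions, summed with an
   identity skip.

Because the overall data flow — image pyramid flowing down, features
flowing down–up through the U — traces an “N”, the configuration with all
three components on is the N-shaped network; with all three off the same
builder yields a plain U-Net, which is the ablation baseline.

## Architecture

### Backbone

The encoder has `depth` levels (default 4); each level applies two 3×3
convolutions (He-uniform weights, zero biases, optional batch
normalisation, ReLU) and a 2×2 max-pool. Channels start at `base_channels`
(default 64) and double per level. The decoder mirrors the encoder:
bilinear ×2 upsampling followed by a 3×3 convolution unit, concatenation
with the (optionally attention-gated) encoder skip, then a two-unit
convolution block. A 1×1 convolution with a sigmoid produces a one-channel
probability map of the input's spatial size, so the network is fully
convolutional: any square input divisible by `2^depth` works.

### Multi-scale input

`multi_scale_pyramid()` builds the pyramid with non-overlapping 2×2 mean
pooling, which preserves global mean intensity exactly at every level. At
encoder levels 2..`depth` the scaled image passes through one 3×3
convolution unit to the incoming channel width and is concatenated with
the pooled features before that level's convolution block (the fusion
style of multi-scale-input U-Net variants).

### Attention guidance

For encoder level \(i\), with scaled image \(I_i\) and feature map
\(F_m\),

\[
g = \sigma\!\big(W_\psi\,\mathrm{ReLU}(W_I I_i + W_F F_m)\big),
\qquad A = g \odot F_m,
\]

where all \(W\) are 1×1 convolutions and \(g\) has one channel broadcast
over all feature channels. Sigmoid gating keeps every coefficient strictly
inside \((0,1)\): the gate re-weights features towards the nodule region
but can never hard-zero them. The intermediate channel width is
`max(C/2, 1)`.

### The SDC bottleneck

The four default branches are dilation stacks \([1]\), \([3]\), \([1,3]\)
and \([1,3,11]\). For stride-1 layers the receptive-field side length of a
cascade is

\[
\mathrm{rf} = 1 + \sum_i (k_i - 1)\,d_i ,
\]

so with 3×3 kernels the branches see 3, 7, 9 and 31 pixels respectively —
this stack assignment is the unique one that realises those four printed
receptive fields with rates growing 1 → 1, 3, 11. Each branch applies its
dilated convolutions in cascade (padding equal to the dilation rate, so
spatial size is preserved; channels constant; ReLU after each), then a 1×1
convolution with ReLU. The block output is the input plus the element-wise
*sum* of the four branch outputs: summation rather than concatenation
keeps the channel count constant, and the identity skip means the block
can only add information. Dilation spaces the kernel taps without adding
weights, so parameter count is independent of the rate
(`conv_param_count(3, C, C)` for every branch layer):

```{r rf}
vapply(sdc_default_branches(),
       function(b) receptive_field(sdc_branch_specs(b)), numeric(1))
```

`receptive_field_empirical()` cross-checks the formula by propagating a
unit impulse through an all-ones-kernel instantiation of the stack and
measuring the nonzero footprint.

## Training protocol

Training minimises pixel-wise binary cross-entropy (computed on the
logits for numerical stability) with Adam. The reference protocol at
512 px is learning rate 1e-4, batch 16, 300 epochs with validation
monitoring; these are the package defaults in `train_config()`. Online
augmentation draws one transform per sample per epoch uniformly from
{identity, rot90, rot180, rot270, hflip, vflip} — the set is closed under
inversion and lossless on integer grids. The checkpoint kept is the one
with the best validation Dice; optional `patience` enables early stopping
(off by default, matching a fixed-epoch run).

At test time, six-view test-time augmentation (`tta_predict()`) predicts
each geometric view, inverse-aligns the six probability maps and averages
them — probabilities are averaged, not binarized masks, and the 0.5
threshold is applied afterwards.

Evaluation uses five metrics from pixel confusion counts: Dice
\(= 2TP/(FP+2TP+FN)\), mean IoU over the two classes
\(\mathrm{mIoU} = \tfrac12\sum_i TP_i/(FP_i+TP_i+FN_i)\), precision,
recall, and F1. Two conventions are fixed here because they matter for
edge cases: (i) when both masks are empty every metric is 1.0 (perfect
agreement on "no nodule"), otherwise a zero denominator scores 0.0;
(ii) F1 is evaluated in its algebraically reduced form
\(2TP/(2TP+FP+FN)\), so `f1_score()` equals `dice()` exactly rather than
to floating-point rounding. Metrics are computed per image and then
averaged (mean ± SD); precision–recall curves pool counts over the set on
a grid of 101 thresholds, with precision defined as 1.0 when no pixel is
predicted.

Cross-validation follows a 5-fold plan: the shuffled indices are cut into
five disjoint test sets, and within each fold the remainder is split 3:1
into train and validation, giving train:val:test = 6:2:2 of the whole set
(±1 sample). The plan is seeded and its partition property is asserted on
every construction.

## The phantom generator

There is no public, redistributable thyroid ultrasound set bundled with
the package, so the pipeline is exercised end-to-end on synthetic
phantoms (`generate_phantom()`) built from a standard B-mode
approximation:

* a smooth background reflectivity field (heavily blurred Gaussian noise
  around intensity 0.72);
* a star-convex nodule whose boundary in circularised elliptical
  coordinates is \(r(\theta) = r_0\,(1 + \sum_j a_j \sin(j\theta +
  \phi_j))\) — harmonics give the irregular margin, `aspect` the
  ellipticity, and `contrast` (default 0.55) multiplies the interior
  intensity, making the nodule hypoechoic;
* Gaussian blur of the reflectivity field (`blur_sigma`, default 1.5 px),
  so the *image* boundary is ambiguous while the *mask* — defined before
  blurring — is crisp, mimicking blurred margins;
* optional bright calcification foci (Poisson count);
* multiplicative unit-mean Gamma speckle (`speckle_shape`, default 16,
  i.e. 25 % relative sd), so local variance scales with local mean as in
  fully developed speckle.

Everything is drawn under one seed and is bit-reproducible.
`generate_dataset()` writes 8-bit PNGs plus a CSV manifest,
byte-identically under a fixed master seed.

What the phantom does *not* emulate: attenuation and shadowing behind the
nodule, anisotropic speckle cells from the point-spread function, probe
artefacts, neighbouring anatomy (trachea, vessels, carotid), or
benign/malignant appearance classes. A model that segments phantoms well
has demonstrably learned "dark connected blob with irregular blurred
boundary under multiplicative noise" — the geometric core of the task —
but no claim about clinical images follows; the phantom's role is to
certify that the architecture, loss, optimiser, augmentation and metrics
interact correctly.

## Desk-scale study conditions

The full 512 px / depth-4 / 64-channel configuration trains at GPU scale;
the package's tests and examples use a scaled-down configuration chosen
once: 64 px phantoms, depth 3, base 8 channels (~417 k parameters), Adam
at 1e-3 (the standard Adam default for small networks; the 512 px default
stays 1e-4), batch 4, 15 epochs within the 30-epoch ceiling, 200 phantoms
split 120/40/40. Under one fixed seed this reaches a held-out Dice of
about 0.95 with six-view TTA, and the validation trajectory is flat after
roughly epoch 10, which is why 15 epochs suffice at this scale. The
ablation harness (`run_ablation()`) trains the four configurations —
plain U-Net, +attention, +multi-scale, +SDC — under identical folds and
seeds; parameter counts increase strictly along that ladder.

## Numerical choices and degenerate inputs

* Batch normalisation after each 3×3 backbone convolution (pre-ReLU),
  with running statistics for evaluation; it stabilises small-batch
  training and can be disabled (`use_batchnorm = FALSE`). The SDC block
  and gate convolutions are plain conv+ReLU.
* Bilinear upsampling uses half-pixel centres (`align_corners = FALSE`
  convention); its adjoint is used in the backward pass.
* Convolution padding is `d·(k−1)/2`, preserving spatial size for odd
  kernels; max-pooling requires even dimensions and reports the offending
  axis otherwise.
* Masks are {0,1} with 1 = nodule, row-major, origin top-left; 8-bit mask
  files must be {0,255} and are binarized at 127; image resizing is
  bilinear, mask resizing nearest-neighbour.
* Weight init is He-uniform with zero biases under an explicit seed; two
  builds with the same seed are identical, and checkpoints restore
  predictions bit-identically.
* A branch stack must be nonempty and all dilation rates ≥ 1; a nodule
  that would leave the phantom frame is retried with a shrunken radius
  (with a message).

## Known limitations

* Pure-CPU training: practical up to roughly 128 px and a few hundred
  images; the 512 px reference protocol is expressible but not practical
  here.
* Single input channel and binary output only; no 3-D volumes.
* The attention gate follows the one-channel-gate design described above;
  published variants with per-channel gates or different intermediate
  widths are not reproduced.
* Dice and F1 are identical by construction for binary masks; tables that
  report them as different numbers imply a different (e.g. pooled or
  probability-weighted) aggregation that this package deliberately does
  not guess at.
* At the desk-scale bottleneck (8×8), the dilation-11 convolution sees
  mostly padding; its branch becomes informative only at larger working
  resolutions.
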