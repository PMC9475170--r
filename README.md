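# sdcnet

Binary segmentation of thyroid nodules in B-mode ultrasound with an
N-shaped fully convolutional encoder–decoder, implemented natively in R.

Thyroid nodules that matter clinically are usually *hypoechoic* — darker
than the surrounding parenchyma — with blurred, irregular margins, embedded
in multiplicative speckle noise. Accurate delineation of the nodule
boundary is the prerequisite for the shape-based features (taller-than-wide,
spiculated margin) used in malignancy assessment. `sdcnet` is aimed at
researchers in medical image analysis who want a compact, fully inspectable
implementation of this architecture family: every primitive — dilated
convolution, pooling, bilinear upsampling, batch normalisation,
reverse-mode differentiation, Adam — is in the package (C++ kernels with an
R tape), so there is no deep-learning framework dependency and every
gradient is testable against finite differences.

## The model

A U-Net backbone (per level: two 3×3 conv + BN + ReLU, then 2×2 max-pool;
channels double per level; mirrored decoder with bilinear ×2 upsampling
and skip connections; 1×1 conv + sigmoid head) extended by three
switchable components:

* **Multi-scale input layer** — an image pyramid built by 2×2 average
  pooling; the scaled image at each level is convolved and concatenated
  with the pooled features entering that level.
* **Attention guidance** — before every skip connection, a one-channel
  gate `g = σ(W_ψ ReLU(W_I I + W_F F_m))` (all 1×1 convolutions)
  multiplies the encoder feature map `F_m`, steering the decoder towards
  the nodule region; gate values lie strictly in (0,1).
* **Stackable dilated convolution (SDC) bottleneck** — four parallel
  cascades of 3×3 dilated convolutions with dilation stacks `[1]`, `[3]`,
  `[1,3]`, `[1,3,11]`, each closed by a 1×1 convolution; branch outputs
  are summed with an identity skip. With the stride-1 receptive-field
  recurrence `rf = 1 + Σ (k−1)·d`, the branches see **3, 7, 9 and 31**
  pixels; dilation adds no parameters.

With all three switches off the builder yields the plain U-Net baseline,
giving a four-row ablation ladder with strictly increasing parameter
counts. Training minimises pixel-wise binary cross-entropy with Adam under
online geometric augmentation (rotations 90/180/270, horizontal and
vertical flips); testing optionally averages six inverse-aligned
prediction maps (test-time augmentation). Evaluation reports Dice, mIoU,
precision, recall and F1 from pixel confusion counts under 5-fold
cross-validation with 6:2:2 train/val/test splits.

Because no public ultrasound dataset ships with the package, a seeded
phantom generator produces ultrasound-like images — smooth tissue field,
star-convex hypoechoic nodule with harmonic boundary perturbations,
Gaussian-blurred margins, optional calcification foci, multiplicative
Gamma speckle — with crisp ground-truth masks, so the whole pipeline
trains and evaluates end-to-end offline.

## Worked example

```r
library(sdcnet)

# receptive fields of the four SDC branches
vapply(sdc_default_branches(),
       function(b) receptive_field(sdc_branch_specs(b)), numeric(1))
#> [1]  3  7  9 31

# 60 seeded speckle phantoms at 64 px
phantoms <- lapply(1:60, function(i)
  generate_phantom(phantom_config(size = 64, seed = i)))
phantoms[[1]]
#> <image_pair> 64x64, 207 foreground px (5.1%)

# 5-fold plan (6:2:2), first fold: 36 train / 12 val / 12 test
plan <- kfold_split(60, k = 5, seed = 1)
f <- plan$folds[[1]]

model <- build_model(arch_config(64, depth = 3, base_channels = 8), seed = 1)
model
#> <nnet_model> depth 3, base 8 ch, input 64px | multiscale=TRUE attention=TRUE sdc=TRUE bn=TRUE | 416,908 parameters

fit <- train_model(model, phantoms[f$train], phantoms[f$val],
                   train_config(lr = 1e-3, batch_size = 4, max_epochs = 8,
                                seed = 1))
round(fit$history$val_dice, 3)
#> [1] 0.155 0.162 0.202 0.329 0.445 0.542 0.566 0.628

evaluate_model(fit$model, phantoms[f$test], use_tta = TRUE)
#> <metric_report> n = 12 images (TTA)
#>   dice      0.8581 +/- 0.0307
#>   miou      0.8575 +/- 0.0243
#>   precision 0.7669 +/- 0.0597
#>   recall    0.9791 +/- 0.0286
#>   f1        0.8581 +/- 0.0307
```

Eight epochs on 36 phantom images already segment held-out phantoms at
Dice ≈ 0.86; the validation-Dice column shows the best-checkpoint logic at
work (the returned model is the epoch-8 one here). With the test-scale
study conditions used in the acceptance suite — 200 phantoms, 15 epochs —
the same configuration reaches Dice ≈ 0.95, and the full model scores at
least as well as its plain U-Net ablation under identical seeds. Dice and
F1 agree exactly because for binary masks the harmonic mean of precision
and recall reduces algebraically to 2TP/(2TP+FP+FN).

A command-line wrapper over the same functions is installed at
`inst/cli/nnet.R` with subcommands `phantom`, `train`, `eval`, `ablate`
and `rf`; every randomized subcommand accepts `--seed` and writes a JSON
config snapshot next to its outputs.

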