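# vpsfda

Source-free domain adaptation of 2-D medical image segmentation models
with **input-specific visual prompts**.

## The problem

A convolutional segmentation model trained on one imaging modality (e.g.
abdominal CT) collapses on another (e.g. MRI): tissue intensities are
remapped, noise and bias fields differ. Often the source images cannot be
shared at all — only the trained model and unlabeled target images are
available (*source-free* unsupervised domain adaptation). `vpsfda`
implements a two-stage answer for BN-bearing 2-D segmentation networks:

1. **Prompting.** An *alignment model* (AM) generates, for every target
   image `x`, an additive image-shaped prompt `AM(x)`. It is trained —
   with the source model completely frozen — by the *batch-normalization
   constraint* (BNC): the batch statistics of the fused images `x + AM(x)`
   inside the source model's BN layers must match the running statistics
   `(μ̄_l, σ̄²_l)` stored there during source training,

   `L_BNC = Σ_l [ mean_c (μ_lc − μ̄_lc)² + mean_c (σ²_lc − σ̄²_lc)² ]`.

   The AM is a double-branch network: an encoder compresses `x` into a
   1,024-dimensional *prompt code*; a synthesis branch of five *prompt
   blocks* (two 3×3 convolutions each, no resampling) turns `x` into the
   prompt, with every kernel *modulated* by a per-input-channel style
   offset derived from the code (`θ̂_ijk = θ_ijk + s_i`) and *demodulated*
   per output channel (`/ sqrt(Σ_{i,k} θ̂² + ε)`) to restore unit variance.
2. **Adaptation.** The target model starts as a parameter copy of the
   source model and is fine-tuned on the fused images with
   confidence-masked cross-entropy against pseudo-labels from the frozen
   teacher, denoised by a double-threshold rule: a pixel predicted as
   foreground class `c` is kept iff `p_c ≥ δ_c` (the k-th largest softmax
   value among pixels claimed by `c`) and `p_c > λ`.

Because real cross-modality corpora need large downloads and GPU-scale
training, the package ships a seeded **synthetic phantom generator**:
paired two-domain datasets with identical per-slice label geometry and a
near-inverted intensity transfer (plus differing noise and bias fields) —
the same *structure* of shift as CT↔MRI, at desk scale.

## Worked example

```r
library(vpsfda)

spec <- phantom_spec(n_slices = 200, seed = 0)   # 64x64, 4 classes
ph   <- phantom_dataset(spec)

# source training on domain A
src <- build_backbone("tiny", num_classes = 4, seed = 0)
src <- train_source(src, ph$images_a[,,1:50], ph$labels[,,1:50],
                    epochs = 14, lr = 2e-3, seed = 1)
mean_dice(src, ph$images_a[,,181:200], ph$labels[,,181:200])  # 0.806
mean_dice(src, ph$images_b[,,181:200], ph$labels[,,181:200])  # 0.185

# stage 1: input-specific prompts from the frozen source model
am <- build_alignment_model(seed = 1)
am <- train_alignment(src, am, ph$images_b, epochs = 2, lr = 1e-3, seed = 2)
mean_dice(src, ph$images_b[,,181:200], ph$labels[,,181:200], am = am)
# 0.552  <- the frozen model, fed prompted images, recovers most of the gap

# stage 2: masked self-training on denoised pseudo-labels
tgt <- adapt(src, am, ph$images_b[,,1:64], epochs = 2, lr = 5e-4, seed = 3)
mean_dice(tgt, ph$images_b[,,181:200], ph$labels[,,181:200], am = am)
# 0.432  <- adapted model, far above the 0.185 source-only baseline
```

The numbers shown are what this exact script prints (seed 0 of the
benchmark protocol). Source-only 0.185 vs held-out source 0.806 is the
domain gap; prompting recovers most of it without touching the model;
adaptation then yields a standalone target model. Pseudo-label noise
(foreground MSE vs ground truth) drops from 0.083 on raw images to 0.032
on fused images — the reason stage 2 has usable supervision.

A command-line interface wraps the same pipeline
(`inst/cli/vpsfda synth | train-source | train-align | pseudo-label |
adapt | evaluate`); see `?vpsfda_cli`.

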