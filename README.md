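# lcmamba

Selective state-space segmentation of liver tumors in 2D CT/MRI slices.

Automatic delineation of hepatocellular carcinoma is hard: lesions are
heterogeneous, often low-contrast against cirrhotic parenchyma, and the
clinically critical small lesions (< 2 cm) are exactly the ones standard
encoder-decoders miss. 3D volumetric models capture context but are too
heavy for routine slice-wise workflows. `lcmamba` implements an efficient
2D alternative built on selective state-space models (Mamba-style), for
researchers who want the mechanism of such a network — the scan, the
attention, the loss — exercisable and testable on a plain CPU, without
external datasets or GPUs.

## The model

**SS2D core.** A diagonal selective state-space layer runs the linear
recurrence

    h_t = Ā h_{t-1} + B̄ x_t,    y_t = C h_t

along four serializations of the feature grid (→ row-major, ← its
reversal, ↓ column-major, ↑ its reversal); the four outputs are
concatenated and linearly projected back to C channels. Parameters come
from the zero-order-hold discretization of a continuous system
A = diag(Λ):

    ā = exp(Δλ),    b̄ = ((exp(Δλ) − 1)/λ) · B      (b̄ → Δ·B as λ → 0)

with Δ, B, C produced from the input by learned linear maps ("selective").
Cost is linear in pixel count: O(HW)·O(C²)·O(N).

**Encoder.** A 3×3 convolutional stem followed by four stages of SS2D
blocks (pre-norm, residual); spatial resolution halves and channel width
grows at each stage transition. Variants: `T` (tiny; depths 2,2,4,2,
widths 96–768, no extra SSM block) and `S` (small; depths 2,2,8,2 plus one
extra block in the deepest stage), plus a `nano` CPU preset for tests and
demonstrations.

**LCAM decoder.** From a coarse initial prediction, each decoder level
derives a reverse-attention map Θ(P) = 1 − P + γ·|∇P| from the upsampled
coarser prediction, modulates transformed encoder features
R = Θ ⊙ δ(f), and combines the refinement logits with the upsampled prior
in logit space. Attention is high where the model is *not* yet confident
and along prediction boundaries.

**Loss.** L = α·BCE + β·softDice + λ·boundaryDice, the last term being the
Dice loss restricted to a ~3-pixel band around the ground-truth lesion
boundary.

Everything — forward passes, analytic backward passes, Adam, the
augmentation pipeline (±15° rotation, flips, resize to the training
resolution) — is implemented in R with the sequential scan recurrence
compiled via Rcpp. A deterministic liver-phantom generator (elliptical
organ, textured parenchyma, lesions of controlled diameter/contrast with
optional necrotic cores) provides the test bed, and the evaluation suite
covers Dice, mIoU, recall, precision, F2, HD95 (exact Euclidean distance
transforms), lesion-size strata (< 2 cm / 2–5 cm / > 5 cm), mean ± SD with
95% CIs, and paired Wilcoxon tests with Holm–Bonferroni correction.

## Worked example

```r
library(lcmamba)

# a 64x64 phantom slice with two lesions
ph <- generate_phantom(phantom_config(seed = 3407))

# a small dataset + a short training run
dir <- tempfile()
generate_dataset(200, c(0.7, 0.15, 0.15), phantom_config(seed = 3407), dir)
res <- train(dir, train_config("nano"))   # ~3 min on one CPU core
res$best_val_dice
#> [1] 0.8221724

# segment and score a held-out slice
ds <- load_manifest(dir)
te <- Filter(function(it) it$split == "test", ds$items)
pr <- predict(res$model, te[[1]]$image)
overlap_metrics(pr$mask, te[[1]]$mask)[["dice"]]

# efficiency of the deployable variants
profile_variant("T")$params_millions   # 14.7577  (M trainable parameters)
profile_variant("T")$flops_giga        # 3.2441   (GFLOPs @ 256x256, 1 MAC = 1 FLOP)
```

Training prints one row per epoch (`loss` is the composite objective
averaged over training slices, `val Dice` the mean validation Dice at
threshold 0.5); over 20 epochs the nano preset's validation Dice rises
from 0 to ≈ 0.82 on the default phantom benchmark, and the held-out test
Dice is ≈ 0.83.

A command-line front end with `generate` / `train` / `predict` /
`evaluate` / `profile` / `compare` subcommands is installed at
`inst/cli/lcmamba`:

```sh
Rscript inst/cli/lcmamba generate --n 200 --out ds --seed 3407
Rscript inst/cli/lcmamba train --manifest ds --variant nano --out run
Rscript inst/cli/lcmamba profile --variant S
```

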