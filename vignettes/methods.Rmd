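---
title: "Methods: selective state-space segmentation of liver lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selective state-space segmentation of liver lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `lcmamba`, the choices
made where the design was genuinely open, the defaults and their
rationale, and what the synthetic benchmark does and does not demonstrate.

## The selective state-space core

Each channel of a feature map is treated as an independent scalar
input to a diagonal linear state-space system with state dimension
$N$. With $A = \mathrm{diag}(\Lambda)$, the zero-order-hold
discretization

$$\bar a = e^{\Delta\lambda}, \qquad
  \bar b = \frac{e^{\Delta\lambda} - 1}{\lambda}\,B$$

turns the continuous system into the recurrence
$h_t = \bar a\,h_{t-1} + \bar b\,x_t$, $y_t = C\,h_t$, evaluated in a
single linear-time sweep. The general matrix form
$(\Delta A)^{-1}(e^{\Delta A} - I)\,\Delta B$ reduces to the expression
above elementwise because $A$ is diagonal (the $\Delta$ cancels); the unit
tests verify this against a dense matrix-exponential oracle. When
$|\Delta\lambda| < 10^{-6}$ we switch to the series limit
$\bar b = \Delta B (1 + \Delta\lambda/2)$: the closed form is a 0/0 at
$\lambda = 0$ but its limit is finite and smooth, and the threshold is
far below any step size the model actually uses.

**Selectivity.** $\Delta$, $B$ and $C$ are functions of the input:
$\Delta = \mathrm{softplus}(x W_\Delta + b_\Delta)$ per channel (shared by
the four scan directions), and per direction $B_t = x_t W_B$,
$C_t = x_t W_C \in \mathbb{R}^N$. $\Lambda$ is a learned per-channel
constant initialized to the decaying pattern $\lambda_{d,n} = -n$,
$n = 1..N$; step sizes initialize log-uniformly in $[10^{-3}, 10^{-1}]$
through the softplus parameterization. These are the standard stable
initializations for diagonal selective models; with
$\mathrm{Re}(\lambda) < 0$ the discretized multiplier satisfies
$|\bar a| < 1$ and the hidden state is bounded by
$\max|\bar b| \max|x| / (1 - \max|\bar a|)$, a property the tests check
directly.

**Four-direction scan (SS2D).** The grid is serialized in raster order
(→), its reversal (←), column-major order (↓) and its reversal (↑); the
scan runs independently in each direction, results are deserialized,
concatenated along channels and projected back to $C$ channels. Any
consistent assignment of the four orders is equivalent up to a
permutation of learned parameters; we fix the convention above. The
trainable block wraps this core with channelwise layer normalization, a
residual connection and a learned per-channel skip ($D\,x$ term). Layer
norm was chosen over batch norm everywhere: it is independent of batch
composition, which keeps single-sample CPU training and eval-mode
determinism trivial.

## Encoder

A 3×3 convolutional stem (stride 4) embeds the slice; four stages of SS2D
blocks follow, each stage ending (except the last) in a 2×2 stride-2
convolution that halves resolution and doubles width. Stage widths
(96, 192, 384, 768) and depths (2,2,4,2) for the tiny variant, (2,2,8,2)
plus one extra deepest-stage block for the small variant, were chosen so
the instantiated models stay inside the published efficiency budgets
(≤ 18.6 M / 38.5 G for T, ≤ 24.2 M / 49.8 G for S at 256×256); the
profiler counts 14.76 M / 3.24 G and 20.89 M / 4.30 G respectively. The
extra-block placement (appended to stage 4) is the cheapest deep
position. Grayscale inputs are replicated to three channels; input
dimensions must be divisible by the overall stride (32 for T/S).

The `nano` preset (stem stride 2, widths 8–64, depths 1,1,2,1, $N = 4$)
exists for CPU-scale training demonstrations and tests. It departs from
the stride-4 stem deliberately: at 64×64 inputs a stride-4 stem leaves
the finest decoder level at 16×16, which caps achievable boundary
accuracy on 8–24 mm lesions; stride 2 keeps the four-stage halving
hierarchy while making the finest prediction level stride 2.

## Reverse-attention decoder (LCAM)

A 1×1 head on the (2×2-pooled) deepest features gives the coarse initial
prediction $P_5$. At each level $i = 4..1$:

1. the coarser prediction is bilinearly upsampled ×2;
2. the attention map $A_i = 1 - P + \gamma\,|\nabla P|$ is computed from
   it, with $|\nabla P|$ the central-difference gradient magnitude under
   edge replication — the only reading of $\nabla P$ that keeps the map
   single-channel. $\gamma$ defaults to 0.5 (exposed in the config):
   large enough that boundary emphasis is visible against the $1-P$ term,
   small enough that attention stays $O(1)$;
3. encoder features pass through $\delta$ = 3×3 conv (to $C/2$ channels) +
   layer norm + ReLU, and are modulated: $R_i = A_i \odot \delta(f_i)$;
4. a 1×1 head turns $R_i$ into refinement logits $p_i$, combined with the
   prior in logit space:
   $P_i = \sigma(p_i + \mathrm{logit}(\mathrm{clamp}(\mathrm{Up}(P_{i+1}),
   \epsilon, 1-\epsilon)))$, $\epsilon = 10^{-4}$.

The combination rule mixes a refinement logit with an upsampled
probability; adding them in logit space is the reading that keeps the
residual-prior semantics in a consistent domain (adding a probability to
a logit has no fixed scale). With zeroed heads the whole cascade
collapses to the $\sigma(0) = 0.5$ fixed point, which the tests use as a
plumbing check. Prediction heads initialize with bias $-2.2$ so the
initial output sits near the ~10% foreground prevalence of the training
data rather than 0.5 — without it the first epochs are spent escaping an
all-background collapse.

During backpropagation the attention map is treated as a constant
(stop-gradient): gradients flow through the feature path and the
logit-space prior, and deep supervision (below) gives every level a
direct loss signal anyway. This is a standard stabilization for
reverse-attention decoders and keeps the backward pass simple; the
finite-difference gradient checks in the test suite confirm that the
neglected path is numerically marginal on realistic inputs.

**Deep supervision.** The loss is applied to every pyramid level
($P_5..P_1$, each bilinearly upsampled to full resolution) with equal
weights. Supervising only the finest level starves the coarse heads whose
predictions seed the attention cascade.

## Objective

$$L = \alpha\,L_{BCE} + \beta\,L_{Dice} + \lambda\,L_{Boundary}$$

with soft Dice over all pixels and the boundary term the same smoothed
Dice restricted to the band $B$: the ground-truth mask XOR its one-pixel
erosion, dilated by one pixel (~3 px straddling the lesion rim; outside
the image counts as background). Defaults $\alpha = \beta = 1$,
$\lambda = 0.5$, $\epsilon = 10^{-6}$: overlap terms carry the main
signal, the boundary term is a half-weight sharpener so it cannot
dominate when the band is a few dozen pixels. $B$ is computed from the
ground truth only (stable targets; a prediction-dependent band would make
the loss landscape nonstationary) and recomputed per augmented sample.
BCE probabilities are clamped at $10^{-7}$. The composite itself addresses
foreground/background imbalance; no extra pixel weighting is applied.

## Training protocol

Adam at learning rate $10^{-4}$, batch 16, inputs resized to 256×256,
random rotation in ±15° plus horizontal/vertical flips, seed 3407,
ReduceLROnPlateau on validation Dice (factor 0.5, patience 5 — the
scheduler is named in the protocol; these are the library-default
settings), early stop after 15 non-improving epochs, best-validation
checkpointing. The `nano` preset trains at 64×64 with learning rate
$10^{-3}$ for 20 epochs: a ~76 k-parameter model taking ~180 optimizer
steps needs a larger step size ($3\times10^{-3}$ was also evaluated and
destabilizes training; $10^{-3}$ is the preset). Augmentation presets:
`none`, `basic` (flips), `full` (rotation + flips).

Determinism: all randomness flows from the config seed through R's RNG;
runs are reproducible on a given platform (floating-point reductions are
deterministic per platform, not bit-identical across BLAS builds).

## Synthetic phantom benchmark

The generator emulates the geometry and first-order photometry of
contrast CT/MRI liver slices: an elliptical organ (~40% of the field of
view) with band-limited Gaussian texture (correlation length 8 px,
amplitude 0.04), lesions as ellipses with equivalent diameter drawn from
a configured mm range, fixed intensity offset (default −0.35, hypodense),
sigmoid margins with half-maximum defining the mask, optional darker
necrotic core (probability 0.2), additive Gaussian noise (SD 0.05), all
on a [0, 1] intensity scale written as 8-bit PNG or float NIfTI. Lesion
axes are $re$ and $r/e$ with $e \in [0.92, 1.08]$, so the enclosed area —
hence the equivalent diameter that drives the size strata — matches the
request up to discretization. Lesions keep ≥ 2 px clear of the organ
border so the boundary band is well defined. Item $i$ of a dataset uses
sub-seed $\mathrm{seed} \oplus i$, making datasets order-independent and
any file regenerable from the manifest alone.

What the phantoms do **not** model: enhancement-phase variability,
infiltrative (non-elliptical) margins, vessels and bile ducts, partial
volume effects, scanner noise spectra, or cirrhotic architectural
distortion. Passing the end-to-end recovery property therefore shows that
the architecture, gradients, optimizer and pipeline work — that the model
can learn lesion appearance from data — not that it reaches any
particular accuracy on clinical images.

Training-demonstration sizes (200 slices at 64×64, 20 epochs for the main
recovery run; 100 slices, 10 epochs, three seeds for the
augmentation-preset comparison; 60 slices, 8 epochs for the
attention-ablation check) were chosen as the smallest configurations
where the properties of interest are driven by learning rather than
noise. At these budgets the default phantom benchmark reaches validation
Dice ≈ 0.82 and held-out Dice ≈ 0.83.

## Evaluation conventions

* Empty/empty masks score Dice = mIoU = 1 and HD95 = 0; exactly one empty
  mask scores Dice 0 and HD95 = image diagonal × spacing (a finite
  penalty). Conventions are recorded in every report.
* mIoU is the two-class mean (foreground and background IoU); foreground
  IoU is exported separately.
* HD95 pools nearest boundary-to-boundary distances in both directions
  (boundary = mask XOR its 1-px erosion; exact Euclidean distance
  transform) and takes the 95th percentile. Per-case means per-slice;
  volume grouping is the caller's responsibility.
* Size strata: Small < 20 mm, Medium 20–50 mm (inclusive), Large > 50 mm
  by equivalent circular diameter $2\sqrt{area/\pi} \cdot$ spacing on
  8-connected components. Stratified Dice is per-lesion on
  component-matched crops (±5 px margin).
* CIs are Student-t on per-case scores (bootstrap percentile available);
  paired comparisons use the two-sided Wilcoxon signed-rank test with
  zero differences dropped, Holm-adjusted across the family.
* Efficiency: exact trainable-parameter count; FLOPs are analytic
  multiply-accumulate counts of one forward pass (1 MAC = 1 FLOP,
  transcendentals count one), reported at 256×256, batch 1.

## Known limitations

* Real-valued states only; complex $\Lambda$ is out of scope.
* No hardware-fused scan: the compiled kernel is sequential per
  direction, fine at CPU-test scale, not a GPU implementation.
* 2D only; no volumetric scanning or inter-slice consistency.
* The pretrained-encoder hook loads name/shape-matched arrays from a
  checkpoint but no weights ship with the package; headline benchmark
  parity with GPU-trained models on clinical datasets is explicitly not
  claimed.
* Binary masks only (tumor vs background).
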