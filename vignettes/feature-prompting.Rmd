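---
title: "Localization-distilled feature prompting: models, losses, and the miniature study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization-distilled feature prompting: models, losses, and the miniature study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldseg)
```

## The problem and the idea

Promptable segmentation models produce a mask conditioned on an auxiliary
cue. In the standard setup the cue is geometric — a bounding box or a few
points — which is a very low-dimensional description of the target: a box
carries no information about shape, appearance, or context, and any noise
in its placement propagates straight into the mask. For structures with
blurred, deformable boundaries (the regime our synthetic generator
emulates), that is a real limitation.

`ldseg` implements the alternative this package is organized around:
**latent feature prompts**. A compact convolutional detector looks at the
image and its multi-scale feature pyramid is projected into the mask
decoder's latent space along two streams:

* a **dense feature prompt** — a pixel-wise map, spatially aligned with
  the image embedding and injected residually,
  $Z_\mathrm{cond} = Z_\mathrm{img} + \alpha\, P_\mathrm{dense}$, with a
  single learnable gate $\alpha$ initialized to exactly 0 so the
  conditioning is strictly additive at the start of training;
* **sparse feature prompts** — $K$ global tokens (default $K = 4$)
  obtained by global average pooling of the fused pyramid followed by a
  two-layer perceptron, which join the decoder's attention alongside the
  output mask token.

Because the quality of these prompts is bounded by the localization
quality of the small detector, the detector is first refined by
**localization distillation (LD)** from a higher-capacity teacher: every
box edge is represented as a categorical distribution over discrete
spatial bins, both networks' distributions are softened by a temperature
$\tau$, and the student matches the teacher's distributions by KL
divergence on a selected subset of anchors.

## Losses

**Generalized softmax.** For logits $z$ and temperature $\tau > 0$,
$p_i = e^{z_i/\tau} / \sum_j e^{z_j/\tau}$ (`generalized_softmax()`),
computed with max-subtraction so extreme logits cannot overflow.
Tempering never decreases the entropy of the result — this softening is
the point: at $\tau = 10$ (the default, the standard LD setting) the
distribution retains the relative plausibility of neighbouring bins
rather than just the argmax.

**LD loss.** `ld_loss()` sums, over the four edges (top, bottom, left,
right), $\mathrm{KL}(p^T_e \,\|\, p^S_e)$ of the tempered distributions.
KL (rather than cross-entropy) is used so the loss is exactly zero at
teacher–student equality; the two differ only by the constant teacher
entropy, so the optimum and gradients are identical. By default the loss
is multiplied by $\tau^2$, the standard compensation for the $1/\tau^2$
gradient attenuation of tempering; a flag disables it.

**Region selection.** Anchors are scored by
$X_k = \max_g \mathrm{DIoU}(\hat b_k, b_g)$, where $\hat b_k$ is the
anchor's decoded box. DIoU is IoU penalized by the squared
centre-distance over the squared enclosing-box diagonal — the standard
definition, stated explicitly in `diou()`'s documentation since it is
used as an assignment affinity here. The **main region** is
$\{k : X_k \ge \alpha_\mathrm{pos}\}$ and the **valuable localization
region** (VLR) is the band
$\{k : \gamma\,\alpha_\mathrm{pos} \le X_k < \alpha_\mathrm{pos}\}$,
disjoint by construction; $\gamma = 1$ makes the band empty. Defaults:
$\alpha_\mathrm{pos} = 0.7$, $\gamma = 0.5$ ($\gamma$ has no canonical
value in the literature beyond its $(0,1]$ range; 0.5 puts a meaningful
band of semi-positive anchors under the threshold). $X_k$ is computed
against the *student's own* decoded boxes: the student is the network
being supervised, so its current geometry decides which anchors carry
localization signal.

One practical deviation matters enough to flag prominently: a *pure*
threshold assigner cannot bootstrap. At random initialization no decoded
box reaches $\mathrm{DIoU} \ge 0.7$ against any ground truth, so the
main region is empty, every box-related loss term is zero, and training
never starts (we verified this directly). The trainer therefore promotes
each ground truth's best-scoring anchor into the main region
(`select_regions(..., ensure_best = TRUE)`), the usual guarantee in
dense-detector label assignment. The default `ensure_best = FALSE`
preserves the strict band semantics and is what the selection contracts
and oracle tests exercise.

**Total phase-1 objective.**
$L = L_\mathrm{det} + \lambda_\mathrm{main} \sum_{k \in \Omega_\mathrm{main}} L^k_\mathrm{LD} + \lambda_\mathrm{vlr} \sum_{k \in \Omega_\mathrm{vlr}} L^k_\mathrm{LD}$,
with $\lambda_\mathrm{main} = \lambda_\mathrm{vlr} = 1$ by default. The
detection loss $L_\mathrm{det}$ is not decomposed by the formulation we
follow, so its composition is this package's choice: objectness BCE over
all anchors (positives = main region), $1 - \mathrm{DIoU}$ on the
decoded boxes of positive anchors, and a distribution-focal
cross-entropy of each edge distribution against soft two-bin targets
(a true distance $d$ in bin units weights its flanking integer bins by
$\lceil d\rceil - d$ and $d - \lfloor d\rfloor$). The KD ablation arm
distills the tempered *objectness* distribution — the miniature detector
is single-class, so the objectness logit plays the role of the class
logits that conventional KD would temper.

**Phase-2 objective.** Soft Dice plus BCE (`seg_loss()`), with the BCE
evaluated in logit space (`max(z,0) - zg + log(1+e^{-|z|})`) so values
and gradients remain exact under saturation, and an $\varepsilon$ guard
in the Dice denominator for empty masks.

## Miniature architectures

No R neural-network framework is available at the tier this package
targets, so `ldseg` carries its own reverse-mode autodiff over plain R
arrays (convolutions via `im2col`/`col2im` in C++; attention, bilinear
resampling, transposed convolutions, and the losses in R). Every layer
type is pinned by finite-difference gradient checks in the test suite.

The full-scale architecture is replaced by stand-ins sized for CPU
minutes; the *mechanism* — distilled features as latent prompts — is the
object under study, not backbone scale:

* **Image encoder**: four stride-2 convolutions to a stride-16,
  $D$-channel embedding. It stands in for a large pretrained encoder and
  is **frozen** (random weights, never updated); residual adapter
  bottlenecks (1×1 down / SiLU / 1×1 up, zero-initialized so they start
  as the identity) after the last three blocks are the only trainable
  part, mirroring parameter-efficient adaptation of a foundation
  encoder. A frozen *random* backbone is the honest stand-in available
  without pretrained weights; the adapters and prompts must supply the
  task signal, which is exactly the regime the ablations probe.
* **Detector backbones**: five stride-2 convolutions plus an FPN neck
  (lateral 1×1, top-down bilinear + add, 3×3 smooth) giving P3/P4/P5 at
  strides 8/16/32. Student base width 8, teacher 20 — the teacher has
  more than 6× the parameters, preserving the teacher–student capacity
  gap that motivates distillation (a parameter-count audit is a test).
* **Detection head**: per cell, one objectness logit and $4 \times B$
  edge-bin logits ($B = 8$ bins, bin width = stride; fewer bins than a
  full-scale detector because a 64 px image spans few strides).
  Decoding takes the expectation over bin indices at $\tau = 1$.
* **Mask decoder**: token set = learned mask token ⊕ sparse prompts ⊕
  optional box-corner tokens; $L = 2$ rounds of token self-attention,
  token→image and image→token cross-attention (2 heads, residual,
  no layer normalization — at this width it proved unnecessary); mask
  logits are the dot product of the MLP-projected mask token with the
  embedding after two 4×4/stride-2 transposed convolutions, bilinearly
  resized to the input resolution. With $L = 0$ the logits reduce
  exactly to the dot product of the initial token with the upsampled
  embedding (tested).
* **Box baseline prompt**: the two corners of the mask-derived tight
  union box, each encoded by fixed sinusoidal position features plus a
  learned corner-type embedding. The baseline arm is therefore prompted
  by *oracle* geometry; feature prompts have to beat an unrealistically
  clean box, which makes the comparison conservative.

Widths default to $C = D = 32$ (fused channels and embedding dim). The
64-wide variant behaves identically in every tested property but
roughly quadruples CPU cost; 32 keeps the complete two-phase study in
minutes. All widths are configurable in `model_spec()`.

## Two-phase training

Phase 1 fits the teacher on the training boxes (plain detection fit,
Adam), then optimizes the student under the combined objective while the
teacher is held fixed; the returned student is frozen. Phase 2 builds
the segmenter around the frozen student and trains **exactly** the
prompt encoder (including $\alpha$), the adapters, and the decoder with
Adam under a closed-form cosine schedule. Both freeze contracts —
teacher unchanged by phase 1, student unchanged by phase 2, and the
phase-2 trainable set — are asserted bit-for-bit in the tests.

The learning-rate *default* in `run_config()` is $10^{-4}$, the
full-scale setting of the protocol this package scales down. The
miniature study itself uses Adam at $2 \times 10^{-3}$ for both phases
(and Adam rather than SGD in phase 1): models this small train stably
and far faster at that rate, and the schedule still anneals to zero.
Epoch defaults are 8 (phase 1) and 12 (phase 2) for the same reason.

All randomness — initialization, batch order, bootstrap — flows through
seeded R RNG; fixed seed and single-threaded execution give bit-identical
training runs (tested).

## The synthetic study

`generate_dataset()` draws 64×64 scenes with 1–3 instances (ellipses,
perturbed star polygons, smoothed blobs; star-shaped by construction so
rasterization is exact), foreground/background means 0.65/0.35, a
Gaussian boundary blur of 1.5 px applied *before* additive noise
(σ = 0.10), so edges are genuinely ambiguous in exactly the way the
method assumes. Instances may touch or partially overlap, exercising the
small-and-crowded regime. Boxes are always derived from the instance
masks by `mask_to_boxes()` — supervision parity between detection and
segmentation is structural, not procedural.

What the generator does *not* emulate: modality-specific texture and
artifacts (speckle, beam hardening), anatomical shape priors,
inter-slice correlation, annotation noise. Passing tests therefore show
the *mechanism* works — feature prompts beat oracle boxes, distilled
prompts beat undistilled ones, more annotation helps — not that any
particular clinical Dice level would be reached.

Splits follow the deterministic protocol: ids sorted lexicographically,
one shuffle with seed 2025, test and validation fractions taken as
ceilings, remainder to train. Annotation budgets (10/20/50/100%) are
prefixes of one seeded shuffle, hence nested; nesting is a design choice
(monotone comparability across budgets) rather than part of the
protocol.

The directional study in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` trains the full pipeline on 200 images (160 in
the script) with seeds {10, 42, 123} and asserts orderings only:
dense+sparse ≥ box baseline, LD-main+VLR ≥ no distillation, and mean
Dice non-decreasing in budget within a 0.02 sampling tolerance. These
problem sizes (6 teacher / 6 phase-1 / 12 phase-2 epochs, batch 8) are
the study's stated conditions.

## Numerical choices and degenerate inputs

* Coordinates are continuous with origin at the top-left corner; the
  pixel at matrix position (r, c) occupies $[c-1, c) \times [r-1, r)$,
  so a single pixel yields a 1×1 box.
* Bilinear resampling uses half-pixel centres (corner alignment off) —
  stated because interpolation dialects change values; the weights are
  exposed in one place and the operation is linear, with the exact
  adjoint as its gradient.
* Convolution padding is zero padding throughout.
* The DIoU term's gradient with respect to the four decoded distances is
  taken by central differences ($h = 10^{-3}$, exact to $O(h^2)$ on a
  piecewise-smooth surface) and then chained analytically through the
  softmax expectation; every other gradient is analytic.
* Prediction binarization is at probability 0.5 (logit 0).
* Metric conventions: both masks empty → Dice = IoU = 1; exactly one
  empty → 0; boundary metrics on empty masks return the image diagonal
  as a flagged sentinel. Boundaries are 8-connected foreground pixels
  with a background (or out-of-image) neighbour, Euclidean metric.
* `connectivity = 8` is the component-labelling default (blob-like
  structures often touch diagonally); 4 is available.
* Bootstrap CIs are percentile intervals over seeded resampled means
  (B = 1000 by default), deterministic given the seed.

## Known limitations

* The frozen encoder is random, not pretrained: absolute Dice levels are
  far below what a pretrained foundation encoder would give, and the
  box-prompt baseline is weaker than it would be with one. Orderings,
  not magnitudes, are the supported conclusions.
* The embedding grid at 64×64 input is 4×4; mask fidelity is limited by
  what the transposed-convolution upscaler can reconstruct from it.
* Single-class detection only; the KD arm's objectness distillation is
  the single-class specialization of classification-logit KD.
* Wilcoxon/Holm significance testing of arm differences is deliberately
  out of scope (standard library statistics, no methodological content
  here); `stats::wilcox.test()` on the per-case tibbles serves if
  needed.

## A worked miniature example

```{r, eval = FALSE}
library(ldseg)

samples <- generate_dataset(scene_config(seed = 2025), 160)
data <- split_dataset(samples, test_frac = 0.2, val_frac = 0.1)

cfg <- run_config(distill_mode = "ld_main_vlr",
                  prompt_mode = "dense+sparse",
                  phase1_epochs = 6, phase2_epochs = 12,
                  lr = 2e-3, phase1_lr = 2e-3)

teacher <- pretrain_teacher(data$train, cfg = cfg, seed = 42)
student <- phase1_distill(teacher, data$train, cfg, seed = 42)
model <- phase2_segment(data$train, cfg, student, seed = 42)

report <- evaluate_model(model, data$test)
glance(report)     # mean Dice/IoU/ACC/HD/ASSD with bootstrap CI
autoplot(report)   # per-case Dice distribution
```
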