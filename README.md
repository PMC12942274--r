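# ldseg

Promptable image segmentation where the prompt is a **learned latent
feature**, not a box — with the prompt generator refined by
**localization distillation** from a higher-capacity teacher. The
package is a complete, desk-scale, CPU-trainable implementation of the
mechanism: miniature encoder/detector/decoder stand-ins with a built-in
reverse-mode autodiff engine, a synthetic generator for the
low-contrast blurred-boundary regime the method targets, the two-phase
training protocol, segmentation metrics with bootstrap confidence
intervals, and the prompt-mode / distillation / annotation-budget
ablation grids. It is written for researchers who want to study or
extend the mechanism itself with fully inspectable, testable code.

## The method in brief

A segmenter `M = Dec(E_img(I), Enc_prompt(P))` usually takes geometric
prompts `P` (boxes, points). Here a compact detector's multi-scale FPN
features `P3/P4/P5` are fused at stride 8,

```
F_fused = Φ_mix(Concat(P3, Up(P4), Up(P5)))
```

and projected into the decoder's latent space along two streams: a
**dense feature prompt** injected residually into the image embedding,

```
Z_cond = Z_img + α · P_dense ,   α learnable, initialized to 0
```

and **K sparse feature prompts** `T_sparse = MLP(GAP(F_fused))`
(default K = 4) that join the mask decoder's attention. The detector is
first sharpened by localization distillation: each box edge
e ∈ {t, b, l, r} is a categorical distribution over B spatial bins,
softened by a generalized softmax `p_i = exp(z_i/τ) / Σ_j exp(z_j/τ)`
(τ = 10), and the student matches the teacher by

```
L_LD = Σ_e KL(p_T^e ‖ p_S^e)
```

on two disjoint anchor sets scored by best DIoU `X_k`: the main region
`{X_k ≥ α_pos}` and the valuable localization region
`{γ·α_pos ≤ X_k < α_pos}` (α_pos = 0.7, γ = 0.5), combined as

```
L_total = L_det + λ_main Σ_main L_LD + λ_vlr Σ_vlr L_LD ,  λ = 1.0
```

Training is decoupled: phase 1 distills the student while the teacher
is frozen; phase 2 freezes the student and the encoder backbone and
trains only the prompt encoder, the encoder adapters, and the mask
decoder with Dice + BCE under a cosine schedule.

## Worked example

```r
library(ldseg)

samples <- generate_dataset(scene_config(seed = 2025), 160)
data <- split_dataset(samples, test_frac = 0.2, val_frac = 0.1)

cfg <- run_config(distill_mode = "ld_main_vlr",
                  prompt_mode = "dense+sparse",
                  phase1_epochs = 6, phase2_epochs = 12,
                  lr = 2e-3, phase1_lr = 2e-3)

teacher <- pretrain_teacher(data$train, cfg = cfg, seed = 42)
student <- phase1_distill(teacher, data$train, cfg, seed = 42)
model   <- phase2_segment(data$train, cfg, student, seed = 42)

glance(evaluate_model(model, data$test))
#> # A tibble: 1 × 8
#>       n  dice   iou   acc    hd  assd dice_lower dice_upper
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl>      <dbl>      <dbl>
#> 1    32 0.524 0.383 0.885  21.4  11.8      0.441      0.601
```

`dice`/`iou`/`acc` are mean overlap scores over the 32 held-out images,
`hd`/`assd` are boundary distances in pixels, and the last two columns
are the 95% bootstrap CI of the mean Dice (B = 1000). Under the same
protocol the box-prompt baseline reaches a mean test Dice of about
0.18, and the dense+sparse arm without distillation about 0.43 (these
are what `scripts/acceptance.R` recomputes). Absolute levels are modest
by design — the frozen miniature encoder is random, not pretrained —
and the supported conclusions are the *orderings* between arms, not
magnitudes.

A full grid over prompt modes, distillation modes, budgets and seeds:

```r
grid <- run_ablation_grid(data, cfg,
                          prompt_modes = c("box", "dense+sparse"),
                          distill_modes = c("none", "ld_main_vlr"),
                          seeds = c(10, 42, 123))
autoplot(grid)
```

A command-line interface wraps the same functions
(`inst/cli/ldseg <synth|distill|train|eval|ablate> --config cfg.yaml ...`).
See the vignette `vignettes/feature-prompting.Rmd` for the models,
losses, defaults, and numerical conventions.

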