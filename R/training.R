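# Two-phase training protocol.
#
# Phase 1 (localization distillation): a high-capacity teacher detector is
# first fitted on the training boxes, then kept fixed while the compact
# student detector is optimized under detection loss plus region-weighted
# distillation. The student backbone-neck is then frozen as a stable
# feature extractor.
#
# Phase 2 (segmentation fine-tuning): the frozen image encoder (adapters
# trainable), the frozen student pyramid, the prompt encoder, and the mask
# decoder form the segmenter; gradients flow only into the prompt encoder,
# the adapters, the decoder, and the injection gate alpha.

#' Run configuration for training and ablation
#'
#' @param prompt_mode One of `"box"`, `"dense"`, `"sparse"`,
#'   `"dense+sparse"`, `"none"`.
#' @param distill_mode One of `"none"`, `"kd"`, `"ld_main"`,
#'   `"ld_main_vlr"`.
#' @param phase1_epochs,phase2_epochs Epoch counts (defaults 8 / 12 at
#'   miniature scale).
#' @param teacher_epochs Teacher pre-training epochs (default 10).
#' @param lr Initial phase-2 learning rate (default 1e-4).
#' @param phase1_lr Detector learning rate (default 2e-3).
#' @param cosine Use a cosine-annealed schedule (default `TRUE`).
#' @param batch_size Images per optimizer step (default 8).
#' @return A list of class `run_config`.
#' @export
run_config <- function(prompt_mode = "dense+sparse", distill_mode = "none",
                       phase1_epochs = 8L, phase2_epochs = 12L,
                       teacher_epochs = 10L, lr = 1e-4, phase1_lr = 2e-3,
                       cosine = TRUE, batch_size = 8L) {
  prompt_mode <- match.arg(prompt_mode,
                           c("box", "dense", "sparse", "dense+sparse", "none"))
  distill_mode <- match.arg(distill_mode,
                            c("none", "kd", "ld_main", "ld_main_vlr"))
  if (phase1_epochs < 1L || phase2_epochs < 1L || teacher_epochs < 1L) {
    abort("epoch counts must be >= 1")
  }
  structure(
    list(prompt_mode = prompt_mode, distill_mode = distill_mode,
         phase1_epochs = as.integer(phase1_epochs),
         phase2_epochs = as.integer(phase2_epochs),
         teacher_epochs = as.integer(teacher_epochs),
         lr = lr, phase1_lr = phase1_lr, cosine = isTRUE(cosine),
         batch_size = as.integer(batch_size)),
    class = "run_config"
  )
}

new_detector <- function(spec, role) {
  pyramid <- new_pyramid(spec, role)
  head <- new_detection_head(spec, fpn_width = pyramid$fpn_width)
  structure(list(pyramid = pyramid, head = head, spec = spec, role = role,
                 frozen = FALSE),
            class = "detector")
}

# Value-only detection forward (no gradients needed downstream).
detect_values <- function(det, image) {
  out <- detection_forward(det$head, pyramid_forward(det$pyramid, image))
  out$levels <- NULL
  out
}

# Shared detector fitting loop. `teacher` (a detector) enables the
# distillation terms of `distill_mode`.
fit_detector <- function(det, samples, cfg, dcfg, distill_mode = "none",
                         teacher = NULL, epochs, lr0) {
  params <- trainable_params(list(det$pyramid, det$head))
  opt <- adam_new(params)
  history <- numeric(epochs)
  n <- length(samples)
  for (ep in seq_len(epochs)) {
    lr <- if (cfg$cosine) cosine_lr(ep, epochs, lr0) else lr0
    ord <- sample(n)
    ep_loss <- 0
    done <- 0L
    ag_zero_grad(params)
    for (i in ord) {
      s <- samples[[i]]
      fwd <- detection_forward(det$head, pyramid_forward(det$pyramid, s$image))
      tch <- if (!is.null(teacher)) detect_values(teacher, s$image) else NULL
      assign <- select_regions(decode_all_anchors(fwd), s$boxes, dcfg,
                               ensure_best = TRUE)
      loss <- det_loss_node(fwd, s$boxes, assign, dcfg, distill_mode, tch)
      ag_backward(loss$node)
      ep_loss <- ep_loss + loss$parts$total
      done <- done + 1L
      if (done %% cfg$batch_size == 0L || done == n) {
        for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / min(cfg$batch_size, done)
        opt <- adam_step(opt, lr)
        ag_zero_grad(params)
      }
    }
    history[ep] <- ep_loss / n
  }
  det$history <- history
  det
}

#' Pre-train the teacher detector
#'
#' A plain detection fit (no distillation) of the high-capacity teacher on
#' the training boxes, used as the fixed distillation source in phase 1.
#'
#' @param samples Training samples (list of `seg_sample`).
#' @param spec A [model_spec()].
#' @param cfg A [run_config()].
#' @param seed RNG seed covering initialization and batching.
#' @return A fitted `detector` (role `"teacher"`).
#' @export
pretrain_teacher <- function(samples, spec = model_spec(),
                             cfg = run_config(), seed = 1L) {
  with_seed(seed, {
    det <- new_detector(spec, "teacher")
    fit_detector(det, samples, cfg, distill_config(), "none", NULL,
                 cfg$teacher_epochs, cfg$phase1_lr)
  })
}

#' Phase 1: localization-distilled student detector
#'
#' Optimizes the compact student under the combined objective
#' `L_det + lambda_main * sum(LD, main) + lambda_vlr * sum(LD, vlr)`
#' according to `cfg$distill_mode` (`"none"`: detection loss only;
#' `"kd"`: adds tempered objectness-logit distillation; `"ld_main"`:
#' adds edge-distribution distillation on the main region;
#' `"ld_main_vlr"`: on both regions). The teacher's parameters are never
#' updated, and the returned student's backbone-neck is frozen, ready to
#' serve as the phase-2 feature extractor.
#'
#' @param teacher A [pretrain_teacher()] result (may be `NULL` for
#'   `distill_mode = "none"`).
#' @param samples Training samples.
#' @param cfg A [run_config()] (supplies `distill_mode`, epochs, lr).
#' @param dcfg A [distill_config()].
#' @param spec A [model_spec()].
#' @param seed RNG seed.
#' @return A fitted, frozen `detector` (role `"student"`).
#' @export
phase1_distill <- function(teacher, samples, cfg = run_config(),
                           dcfg = distill_config(), spec = model_spec(),
                           seed = 1L) {
  if (!cfg$distill_mode %in% c("none", "kd", "ld_main", "ld_main_vlr")) {
    abort(paste0("unknown distill mode: ", cfg$distill_mode))
  }
  if (is.null(teacher) && cfg$distill_mode != "none") {
    abort("distillation modes other than 'none' require a teacher")
  }
  student <- with_seed(seed, {
    det <- new_detector(spec, "student")
    fit_detector(det, samples, cfg, dcfg, cfg$distill_mode, teacher,
                 cfg$phase1_epochs, cfg$phase1_lr)
  })
  set_trainable(list(student$pyramid, student$head), FALSE)
  student$frozen <- TRUE
  student
}

# The tight box around everything annotated in the sample (used as the
# geometric prompt of the baseline arm).
union_box <- function(sample) {
  b <- sample$boxes
  boxes(min(b$xmin), min(b$ymin), max(b$xmax), max(b$ymax))
}

# Forward pass of the full segmenter on one sample; returns the mask
# logits node. Student features are consumed as fixed arrays (the student
# is frozen in phase 2, so no gradient may flow into it).
segmenter_forward <- function(model, sample) {
  mode <- model$prompt_mode
  z_img <- image_encoder(model$encoder, sample$image, adapters = TRUE)
  tokens <- list()
  z_cond <- z_img
  if (mode %in% c("dense", "sparse", "dense+sparse")) {
    pyr <- lapply(pyramid_forward(model$student$pyramid, sample$image),
                  function(p) p$value)
    fused <- fuse_pyramid(model$prompt_encoder, pyr)
    if (mode %in% c("dense", "dense+sparse")) {
      z_cond <- inject_dense(z_img, dense_prompt(model$prompt_encoder, fused),
                             model$prompt_encoder$alpha)
    }
    if (mode %in% c("sparse", "dense+sparse")) {
      tokens <- c(tokens, list(sparse_prompt(model$prompt_encoder, fused)))
    }
  }
  if (mode == "box") {
    tokens <- c(tokens, list(box_prompt_tokens(model$prompt_encoder,
                                               union_box(sample))))
  }
  mask_decoder(model$decoder, z_cond, tokens)
}

#' Phase 2: segmentation fine-tuning
#'
#' Builds the segmenter (frozen-backbone image encoder with trainable
#' adapters, prompt encoder, mask decoder) around an optionally supplied
#' frozen student detector, and trains it with the Dice + BCE objective
#' under a cosine-annealed learning rate. The trainable set is exactly
#' the prompt encoder (including the gate `alpha`), the adapters, and the
#' decoder; the encoder backbone and the student pyramid receive no
#' updates.
#'
#' @param samples Training samples.
#' @param cfg A [run_config()] (supplies `prompt_mode`, epochs, lr,
#'   batch size).
#' @param student A frozen phase-1 `detector`; required for the feature
#'   prompt modes, ignored for `"box"`/`"none"`.
#' @param spec A [model_spec()].
#' @param seed RNG seed.
#' @return A fitted segmenter of class `ldseg_model`.
#' @export
phase2_segment <- function(samples, cfg = run_config(), student = NULL,
                           spec = model_spec(), seed = 1L) {
  needs_student <- cfg$prompt_mode %in% c("dense", "sparse", "dense+sparse")
  if (needs_student && is.null(student)) {
    abort(paste0("prompt mode '", cfg$prompt_mode,
                 "' requires a distilled student detector"))
  }
  with_seed(seed, {
    model <- structure(
      list(encoder = new_image_encoder(spec),
           prompt_encoder = new_prompt_encoder(spec),
           decoder = new_mask_decoder(spec),
           student = if (needs_student) student else NULL,
           prompt_mode = cfg$prompt_mode, spec = spec, cfg = cfg),
      class = "ldseg_model"
    )
    params <- trainable_params(list(model$encoder, model$prompt_encoder,
                                    model$decoder))
    opt <- adam_new(params)
    n <- length(samples)
    history <- numeric(cfg$phase2_epochs)
    for (ep in seq_len(cfg$phase2_epochs)) {
      lr <- if (cfg$cosine) cosine_lr(ep, cfg$phase2_epochs, cfg$lr) else cfg$lr
      ord <- sample(n)
      ep_loss <- 0
      done <- 0L
      ag_zero_grad(params)
      for (i in ord) {
        s <- samples[[i]]
        loss <- seg_loss(segmenter_forward(model, s), s$union_mask)
        ag_backward(loss)
        ep_loss <- ep_loss + loss$value
        done <- done + 1L
        if (done %% cfg$batch_size == 0L || done == n) {
          for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / min(cfg$batch_size, done)
          opt <- adam_step(opt, lr)
          ag_zero_grad(params)
        }
      }
      history[ep] <- ep_loss / n
    }
    model$history <- history
    model
  })
}

#' Predict a binary mask for one sample
#'
#' Runs the segmenter forward and binarizes the mask probabilities at 0.5
#' (logit 0).
#'
#' @param model An [phase2_segment()] result.
#' @param sample A `seg_sample`.
#' @param binarize Return 0/1 (default) rather than logits.
#' @return A matrix at the input resolution.
#' @export
predict_mask <- function(model, sample, binarize = TRUE) {
  logits <- segmenter_forward(model, sample)$value
  if (binarize) matrix(as.integer(logits > 0), nrow(logits), ncol(logits))
  else logits
}

#' Evaluate a segmenter on held-out samples
#'
#' Computes per-case Dice, IoU, pixel accuracy, Hausdorff distance and
#' ASSD against the union ground-truth mask, plus bootstrap confidence
#' intervals for the mean Dice and IoU.
#'
#' @param model An [phase2_segment()] result.
#' @param samples Test samples.
#' @param boot_B Bootstrap resamples (default 1000).
#' @param boot_seed Bootstrap seed (default 1).
#' @return An `eval_report`: list with `cases` (one tibble row per
#'   sample), `summary` (means and 95% CI bounds), and `meta`.
#' @export
evaluate_model <- function(model, samples, boot_B = 1000L, boot_seed = 1L) {
  cases <- dplyr::bind_rows(lapply(samples, function(s) {
    pred <- predict_mask(model, s)
    tibble(id = s$id,
           dice = dice_score(pred, s$union_mask),
           iou = iou_score(pred, s$union_mask),
           acc = pixel_accuracy(pred, s$union_mask),
           hd = as.numeric(hausdorff_distance(pred, s$union_mask)),
           assd = as.numeric(assd(pred, s$union_mask)))
  }))
  ci_d <- bootstrap_ci(cases$dice, boot_B, boot_seed)
  ci_i <- bootstrap_ci(cases$iou, boot_B, boot_seed)
  summary <- tibble(
    metric = c("dice", "iou", "acc", "hd", "assd"),
    mean = c(mean(cases$dice), mean(cases$iou), mean(cases$acc),
             mean(cases$hd), mean(cases$assd)),
    ci_lower = c(ci_d[1L], ci_i[1L], NA, NA, NA),
    ci_upper = c(ci_d[2L], ci_i[2L], NA, NA, NA)
  )
  structure(list(cases = cases, summary = summary,
                 meta = list(prompt_mode = model$prompt_mode,
                             n = length(samples))),
            class = "eval_report")
}
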