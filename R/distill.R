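#' Configuration for localization distillation
#'
#' Bundles the hyperparameters of the distillation objective. The defaults
#' follow the standard localization-distillation recipe: temperature 10 and
#' unit weights on both distillation regions.
#'
#' @param temperature Distillation temperature \eqn{\tau > 0} (default 10).
#'   Values above 1 soften the bin distributions so they carry relative
#'   uncertainty, not just the argmax.
#' @param lambda_main,lambda_vlr Nonnegative weights on the main-region and
#'   valuable-localization-region distillation sums (default 1.0 each).
#' @param alpha_pos Positive DIoU threshold in (0, 1]; anchors whose best
#'   DIoU reaches it form the main region (default 0.7).
#' @param gamma Bandwidth factor in (0, 1] for the valuable localization
#'   region: anchors with best DIoU in `[gamma * alpha_pos, alpha_pos)`
#'   (default 0.5; `gamma = 1` makes the band empty).
#' @param tau_square_rescale Multiply distillation losses by
#'   \eqn{\tau^2} so their gradient magnitude is comparable to the
#'   untempered loss (default `TRUE`).
#' @return A validated list of class `distill_config`.
#' @export
distill_config <- function(temperature = 10, lambda_main = 1, lambda_vlr = 1,
                           alpha_pos = 0.7, gamma = 0.5,
                           tau_square_rescale = TRUE) {
  if (temperature <= 0) abort("`temperature` must be > 0")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must lie in (0, 1]")
  if (alpha_pos <= 0 || alpha_pos > 1) abort("`alpha_pos` must lie in (0, 1]")
  if (lambda_main < 0 || lambda_vlr < 0) abort("region weights must be >= 0")
  structure(
    list(temperature = temperature, lambda_main = lambda_main,
         lambda_vlr = lambda_vlr, alpha_pos = alpha_pos, gamma = gamma,
         tau_square_rescale = tau_square_rescale),
    class = "distill_config"
  )
}

#' Generalized (tempered) softmax
#'
#' `p_i = exp(z_i / tau) / sum_j exp(z_j / tau)`, stabilized by subtracting
#' the maximum logit. At `tau = 1` this is the standard softmax; larger
#' temperatures flatten the distribution.
#'
#' @param z Finite numeric vector of logits.
#' @param tau Temperature, > 0.
#' @return A probability vector of the same length (sums to 1).
#' @export
generalized_softmax <- function(z, tau = 1) {
  if (tau <= 0) abort("`tau` must be > 0")
  if (!all(is.finite(z))) abort("logits must be finite")
  z <- z / tau
  e <- exp(z - max(z))
  e / sum(e)
}

# KL(p || q) with 0 log 0 = 0; both are probability vectors.
kl_div <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz])))
}

as_edge_logits <- function(x) {
  if (is.list(x) && !is.matrix(x)) {
    lens <- lengths(x)
    if (length(x) != 4L || length(unique(lens)) != 1L) {
      abort("edge logits must be four vectors with a common bin count")
    }
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || nrow(x) != 4L) abort("edge logits must be a 4 x B matrix")
  x
}

#' Localization-distillation loss between edge distributions
#'
#' For each box edge (top, bottom, left, right), the student and teacher
#' logits are tempered by [generalized_softmax()] at the shared temperature
#' and compared by KL divergence `KL(teacher || student)`; the four edge
#' terms are summed. The loss is zero exactly when the tempered student
#' matches the tempered teacher on every edge, and is otherwise positive.
#' With `tau_square_rescale` the sum is multiplied by `temperature^2`
#' (standard practice, so gradient scale does not vanish as `1/tau^2`).
#'
#' @param student,teacher 4 x B matrices of edge logits (rows top, bottom,
#'   left, right), sharing the same bin count B.
#' @param cfg A [distill_config()].
#' @return A nonnegative scalar.
#' @export
ld_loss <- function(student, teacher, cfg = distill_config()) {
  s <- as_edge_logits(student)
  t <- as_edge_logits(teacher)
  if (ncol(s) != ncol(t)) abort("student and teacher must share the bin count B")
  tau <- cfg$temperature
  loss <- 0
  for (e in 1:4) {
    loss <- loss + kl_div(generalized_softmax(t[e, ], tau),
                          generalized_softmax(s[e, ], tau))
  }
  if (isTRUE(cfg$tau_square_rescale)) loss <- loss * tau^2
  loss
}

#' Classification-logit distillation loss
#'
#' Conventional knowledge distillation on class logits: tempered KL
#' divergence `KL(teacher || student)` with the same temperature and
#' rescaling convention as [ld_loss()]. Used only in the distillation
#' ablation's KD arm.
#'
#' @param student,teacher Numeric logit vectors of equal length.
#' @param tau Temperature (> 0).
#' @param tau_square_rescale Multiply by `tau^2` (default `TRUE`).
#' @return A nonnegative scalar.
#' @export
kd_class_loss <- function(student, teacher, tau = 10,
                          tau_square_rescale = TRUE) {
  if (length(student) != length(teacher)) {
    abort("student and teacher must have the same number of classes")
  }
  loss <- kl_div(generalized_softmax(teacher, tau),
                 generalized_softmax(student, tau))
  if (isTRUE(tau_square_rescale)) loss <- loss * tau^2
  loss
}

#' Select main and valuable localization regions
#'
#' Scores every anchor by its best DIoU against the ground-truth boxes
#' (`X_k = max_g DIoU(decoded_k, gt_g)`) and partitions anchors into the
#' main region (`X_k >= alpha_pos`), the valuable localization region
#' (`gamma * alpha_pos <= X_k < alpha_pos`), and the rest. The two regions
#' are disjoint by construction; `gamma = 1` always yields an empty VLR.
#' Ties in the best-matching ground truth resolve to the lowest index.
#'
#' With `ensure_best = TRUE`, the best-scoring anchor of each ground-truth
#' box is promoted into the main region even if its DIoU falls below
#' `alpha_pos`. This is the trainer's assigner: a pure threshold rule
#' assigns no positives at all early in training, when decoded boxes are
#' still far from any ground truth, and learning cannot start. The default
#' (`FALSE`) keeps the strict band semantics.
#'
#' @param anchor_boxes Decoded per-anchor boxes: a box tibble or a plain
#'   n x 4 matrix (xmin, ymin, xmax, ymax).
#' @param gt A box tibble of ground-truth boxes (may have zero rows: then
#'   all scores are the sentinel -1 and both regions are empty).
#' @param cfg A [distill_config()].
#' @param ensure_best Promote each ground truth's argmax anchor into the
#'   main region (default `FALSE`).
#' @return A tibble of class `region_assignment` with one row per anchor:
#'   `anchor`, `score` (best DIoU), `gt_index` (best-matching ground truth,
#'   `NA` if none), and `region` (`"main"`, `"vlr"`, or `"none"`).
#' @export
select_regions <- function(anchor_boxes, gt, cfg = distill_config(),
                           ensure_best = FALSE) {
  am <- if (is.matrix(anchor_boxes)) anchor_boxes else {
    box_matrix(validate_boxes(anchor_boxes))
  }
  if (nrow(am) == 0L) abort("need at least one anchor")
  n <- nrow(am)
  if (nrow(gt) == 0L) {
    out <- tibble(anchor = seq_len(n), score = -1, gt_index = NA_integer_,
                  region = "none")
    class(out) <- c("region_assignment", class(out))
    return(out)
  }
  gm <- if (is.matrix(gt)) gt else box_matrix(validate_boxes(gt))
  sc <- diou_matrix(am, gm)
  best <- max.col(sc, ties.method = "first")
  x <- sc[cbind(seq_len(n), best)]
  region <- rep("none", n)
  region[x >= cfg$gamma * cfg$alpha_pos & x < cfg$alpha_pos] <- "vlr"
  region[x >= cfg$alpha_pos] <- "main"
  if (isTRUE(ensure_best)) {
    for (g in seq_len(nrow(gm))) {
      k <- which.max(sc[, g])
      region[k] <- "main"
      best[k] <- g
    }
  }
  out <- tibble(anchor = seq_len(n), score = x, gt_index = as.integer(best),
                region = region)
  class(out) <- c("region_assignment", class(out))
  out
}

#' Total distillation objective
#'
#' Combines a detection loss with region-weighted localization-distillation
#' sums:
#' `L_total = L_det + lambda_main * sum(LD over main) +
#'  lambda_vlr * sum(LD over VLR)`.
#' Empty regions contribute zero, so with both weights zero (or no
#' assigned anchors) the total reduces to the detection loss.
#'
#' @param det_loss Scalar detection loss.
#' @param ld_per_anchor Numeric vector of per-anchor LD losses, indexed like
#'   the rows of `assignment`; only entries for anchors in a region are
#'   read.
#' @param assignment A [select_regions()] result.
#' @param cfg A [distill_config()].
#' @return A scalar.
#' @export
total_distill_loss <- function(det_loss, ld_per_anchor, assignment,
                               cfg = distill_config()) {
  main <- which(assignment$region == "main")
  vlr <- which(assignment$region == "vlr")
  if (length(union(main, vlr)) &&
      any(is.na(ld_per_anchor[union(main, vlr)]))) {
    abort("LD losses must be available for every anchor in a region")
  }
  det_loss +
    cfg$lambda_main * sum(ld_per_anchor[main]) +
    cfg$lambda_vlr * sum(ld_per_anchor[vlr])
}
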