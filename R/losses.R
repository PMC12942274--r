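# Training objectives. Gradients w.r.t. the network outputs are computed
# analytically here (softmax cross-entropy, KL, BCE identities) and
# attached to the graph through ag_custom(); the one exception is the
# DIoU box term, whose gradient w.r.t. the four decoded edge distances is
# taken by central finite differences (h = 1e-3) before chaining
# analytically through the softmax expectation - the DIoU surface is
# piecewise smooth and four scalars per positive anchor keep this exact
# to O(h^2) at negligible cost.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Soft distribution-focal targets: distance d (in bins) spreads over its
# two flanking integer bins with weights (ceil(d)-d, d-floor(d)).
dfl_target <- function(d, B) {
  d <- min(max(d, 0), B - 1)
  lo <- floor(d); hi <- ceiling(d)
  w <- numeric(B)
  if (lo == hi) w[lo + 1] <- 1 else {
    w[lo + 1] <- hi - d
    w[hi + 1] <- d - lo
  }
  w
}

# Core detection (+ optional distillation) objective over a detection
# output. Returns the loss value split into parts and the gradient matrix
# over the flattened head outputs (n_anchors x (1 + 4B)).
det_loss_parts <- function(det, gt, assignment, cfg = distill_config(),
                           distill_mode = "none", teacher_det = NULL) {
  B <- det$bins
  n <- length(det$obj)
  G <- matrix(0, n, 1L + 4L * B)
  pos <- which(assignment$region == "main")
  n_pos <- length(pos)

  # objectness BCE, positives are the main region
  tgt <- as.numeric(assignment$region == "main")
  p_obj <- sigmoid(det$obj)
  eps <- 1e-12
  l_obj <- -mean(tgt * log(p_obj + eps) + (1 - tgt) * log(1 - p_obj + eps))
  G[, 1L] <- (p_obj - tgt) / n

  l_box <- 0; l_dfl <- 0
  if (n_pos > 0L) {
    gtm <- box_matrix(gt)
    for (k in pos) {
      g <- gtm[assignment$gt_index[k], ]
      stride <- det$anchors$stride[k]
      cx <- det$anchors$cx[k]; cy <- det$anchors$cy[k]
      zmat <- matrix(det$edges[k, ], 4L, B, byrow = TRUE)
      pmat <- t(apply(zmat, 1L, function(z) generalized_softmax(z, 1)))
      mu <- as.numeric(pmat %*% (seq_len(B) - 1))    # decoded bins, t/b/l/r
      d <- mu * stride
      # DIoU box term: dL/dd by central differences, then chain to logits
      gm1 <- matrix(g, 1L, 4L)
      diou_of <- function(dd) {
        diou_num(matrix(c(cx - dd[3L], cy - dd[1L], cx + dd[4L], cy + dd[2L]),
                        1L, 4L), gm1)
      }
      l_box <- l_box + (1 - diou_of(d))
      h <- 1e-3
      for (e in 1:4) {
        dp <- d; dp[e] <- dp[e] + h
        dm <- d; dm[e] <- dm[e] - h
        dl_dd <- -(diou_of(dp) - diou_of(dm)) / (2 * h)
        # d(expectation)/dz_i = p_i * (i - mu) * stride
        gz <- dl_dd * stride * pmat[e, ] * ((seq_len(B) - 1) - mu[e]) / n_pos
        cols <- 1L + (e - 1L) * B + seq_len(B)
        G[k, cols] <- G[k, cols] + gz
      }
      # distribution-focal cross-entropy against the true edge distances
      tdist <- c(cy - g[2L], g[4L] - cy, cx - g[1L], g[3L] - cx) / stride
      for (e in 1:4) {
        w <- dfl_target(tdist[e], B)
        l_dfl <- l_dfl + -sum(w * log(pmat[e, ] + eps))
        cols <- 1L + (e - 1L) * B + seq_len(B)
        G[k, cols] <- G[k, cols] + (pmat[e, ] - w) / n_pos
      }
    }
    l_box <- l_box / n_pos
    l_dfl <- l_dfl / n_pos
  }

  # distillation terms
  tau <- cfg$temperature
  resc <- if (isTRUE(cfg$tau_square_rescale)) tau^2 else 1
  l_ld_main <- 0; l_ld_vlr <- 0; l_kd <- 0
  ld_per_anchor <- rep(NA_real_, n)
  if (distill_mode %in% c("ld_main", "ld_main_vlr") && !is.null(teacher_det)) {
    sel <- which(assignment$region == "main")
    if (distill_mode == "ld_main_vlr") {
      sel <- c(sel, which(assignment$region == "vlr"))
    }
    for (k in sel) {
      lam <- if (assignment$region[k] == "main") cfg$lambda_main else cfg$lambda_vlr
      lk <- 0
      for (e in 1:4) {
        cols <- (e - 1L) * B + seq_len(B)
        ps <- generalized_softmax(det$edges[k, cols], tau)
        pt <- generalized_softmax(teacher_det$edges[k, cols], tau)
        lk <- lk + kl_div(pt, ps) * resc
        # d/dz of tau^2-rescaled KL(pt || softmax(z/tau)) = tau * (ps - pt)
        G[k, 1L + cols] <- G[k, 1L + cols] + lam * (resc / tau) * (ps - pt)
      }
      ld_per_anchor[k] <- lk
      if (assignment$region[k] == "main") l_ld_main <- l_ld_main + lk
      else l_ld_vlr <- l_ld_vlr + lk
    }
  } else if (distill_mode == "kd" && !is.null(teacher_det)) {
    # tempered binary KL on the objectness logits, averaged over anchors
    ps <- sigmoid(det$obj / tau)
    pt <- sigmoid(teacher_det$obj / tau)
    l_kd <- resc * mean(pt * log((pt + eps) / (ps + eps)) +
                          (1 - pt) * log((1 - pt + eps) / (1 - ps + eps)))
    G[, 1L] <- G[, 1L] + (resc / tau) * (ps - pt) / n
  }

  det_loss <- l_obj + l_box + l_dfl
  total <- det_loss + cfg$lambda_main * l_ld_main + cfg$lambda_vlr * l_ld_vlr +
    l_kd
  list(total = total, det = det_loss, obj = l_obj, box = l_box, dfl = l_dfl,
       ld_main = l_ld_main, ld_vlr = l_ld_vlr, kd = l_kd,
       ld_per_anchor = ld_per_anchor, grad = G)
}

# Attach analytic gradients to the per-level head output nodes and return
# a scalar loss node plus the loss parts.
det_loss_node <- function(det, gt, assignment, cfg = distill_config(),
                          distill_mode = "none", teacher_det = NULL) {
  parts <- det_loss_parts(det, gt, assignment, cfg, distill_mode, teacher_det)
  offs <- c(0, cumsum(det$n_per_level))
  nodes <- vector("list", length(det$levels))
  for (i in seq_along(det$levels)) {
    d <- dim(det$levels[[i]]$value)
    rows <- (offs[i] + 1):offs[i + 1]
    Gl <- parts$grad[rows, , drop = FALSE]
    dim(Gl) <- d
    val <- if (i == 1L) parts$total else 0
    nodes[[i]] <- ag_custom(det$levels[[i]], val, Gl)
  }
  list(node = ag_sum_nodes(nodes), parts = parts)
}

#' Detection loss for a miniature detector
#'
#' The composite objective supervising the detection branch: binary
#' cross-entropy on objectness (positives are the assignment's main
#' region), `1 - DIoU` on the decoded boxes of positive anchors, and a
#' soft two-bin (distribution-focal) cross-entropy of each edge
#' distribution against the true edge distance. With no positive anchors
#' the box and bin terms contribute exactly zero and only the objectness
#' term remains.
#'
#' @param det A [detection_forward()] output.
#' @param gt Ground-truth box tibble.
#' @param assignment A [select_regions()] result for these anchors.
#' @return A scalar (numeric). Use the internal graph variant for
#'   training.
#' @export
detection_loss <- function(det, gt, assignment) {
  det_loss_parts(det, gt, assignment)$det
}

#' Segmentation loss: soft Dice plus binary cross-entropy
#'
#' `1 - 2*sum(p*g) / (sum(p) + sum(g) + eps)` on the sigmoid probabilities
#' plus mean BCE on the logits. The epsilon guard keeps the Dice term
#' defined for an empty ground-truth mask.
#'
#' @param logits Mask logits (autodiff node or matrix).
#' @param gt_mask Binary ground-truth matrix of the same shape.
#' @param eps Dice stabilizer (default 1e-6).
#' @return An autodiff node (scalar); `ag_value()` gives the number.
#' @export
seg_loss <- function(logits, gt_mask, eps = 1e-6) {
  logits <- as_ag(logits)
  if (!identical(dim(logits$value)[1:2], dim(gt_mask)[1:2])) {
    abort("logits and mask shapes must match")
  }
  z <- as.numeric(logits$value)
  g <- as.numeric(gt_mask != 0)
  p <- sigmoid(z)
  n <- length(p)
  S <- sum(p) + sum(g) + eps
  T2 <- 2 * sum(p * g)
  l_dice <- 1 - T2 / S
  # BCE evaluated in logit space (exact and stable under saturation)
  l_bce <- mean(pmax(z, 0) - z * g + log1p(exp(-abs(z))))
  # d/dp of the Dice term, then chain through the sigmoid
  dp <- -(2 * g * S - T2) / S^2
  grad <- (dp * p * (1 - p)) + (p - g) / n
  dim(grad) <- dim(logits$value)
  ag_custom(logits, l_dice + l_bce, grad)
}
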