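#' Overlap metrics for binary masks
#'
#' Standard definitions: Dice `2|A n B| / (|A| + |B|)`, IoU (Jaccard)
#' `|A n B| / |A u B|`, and pixel accuracy. Convention for degenerate
#' inputs: if both masks are empty, Dice = IoU = 1 (perfect agreement);
#' if exactly one is empty, Dice = IoU = 0. The identity
#' `Dice = 2 * IoU / (1 + IoU)` holds for every pair.
#'
#' @param pred,gt Binary matrices of equal shape (0/1 or logical).
#' @return A scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  ab <- mask_pair(pred, gt)
  if (ab$na + ab$nb == 0) return(1)
  2 * ab$inter / (ab$na + ab$nb)
}

#' @rdname dice_score
#' @export
iou_score <- function(pred, gt) {
  ab <- mask_pair(pred, gt)
  if (ab$na + ab$nb == 0) return(1)
  uni <- ab$na + ab$nb - ab$inter
  if (uni == 0) 1 else ab$inter / uni
}

#' @rdname dice_score
#' @export
pixel_accuracy <- function(pred, gt) {
  ab <- mask_pair(pred, gt)
  mean(ab$a == ab$b)
}

mask_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) abort("masks must have equal shape")
  a <- pred != 0
  b <- gt != 0
  list(a = a, b = b, na = sum(a), nb = sum(b), inter = sum(a & b))
}

# 8-connected boundary pixels of a mask: foreground pixels with at least
# one background (or out-of-image) neighbour. Returns pixel-centre
# coordinates (x, y).
boundary_points <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  all_n <- pad[1:H, 1:W] & pad[1:H, 2:(W + 1L)] & pad[1:H, 3:(W + 2L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)] &
    pad[3:(H + 2L), 1:W] & pad[3:(H + 2L), 2:(W + 1L)] & pad[3:(H + 2L), 3:(W + 2L)]
  idx <- which(inner & !all_n, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 0.5, y = idx[, 1L] - 0.5)
}

# Directed mean and max of min Euclidean distances from points a to b.
directed_dists <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  mins <- sqrt(apply(d2, 1L, min))
  list(mean = mean(mins), max = max(mins))
}

#' Boundary distance metrics: Hausdorff and ASSD
#'
#' Computed on the 8-connected boundary pixels of each mask with the
#' Euclidean metric. The Hausdorff distance is the maximum of the two
#' directed max-min boundary distances; the average symmetric surface
#' distance (ASSD) averages the two directed mean boundary distances.
#' Identical masks score 0. If either mask is empty the image diagonal is
#' returned as a sentinel, with attribute `empty = TRUE`.
#'
#' @param pred,gt Binary matrices of equal shape.
#' @return Distance in pixels.
#' @export
hausdorff_distance <- function(pred, gt) {
  bd <- boundary_pair(pred, gt)
  if (is.null(bd)) return(empty_sentinel(pred))
  max(directed_dists(bd$a, bd$b)$max, directed_dists(bd$b, bd$a)$max)
}

#' @rdname hausdorff_distance
#' @export
assd <- function(pred, gt) {
  bd <- boundary_pair(pred, gt)
  if (is.null(bd)) return(empty_sentinel(pred))
  (directed_dists(bd$a, bd$b)$mean + directed_dists(bd$b, bd$a)$mean) / 2
}

boundary_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) abort("masks must have equal shape")
  a <- boundary_points(pred)
  b <- boundary_points(gt)
  if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
  list(a = a, b = b)
}

empty_sentinel <- function(mask) {
  structure(sqrt(nrow(mask)^2 + ncol(mask)^2), empty = TRUE)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Non-parametric bootstrap of per-case scores: `B` seeded resamples with
#' replacement, percentile bounds of the resampled means. Deterministic
#' given the seed; constant scores give a zero-width interval.
#'
#' @param scores Numeric vector of per-case scores (length >= 2).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, B = 1000L, seed = 1L, conf = 0.95) {
  if (length(scores) < 2L) abort("need at least two per-case scores")
  if (B < 1L) abort("`B` must be >= 1")
  means <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      mean(sample(scores, length(scores), replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}
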