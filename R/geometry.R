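#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort
#' @importFrom utils head tail
NULL

# Coordinate convention: continuous pixel coordinates with the origin at the
# top-left image corner, x rightward and y downward. The pixel stored at
# matrix position (row r, col c) (1-based R indexing) occupies the half-open
# cell [c-1, c) x [r-1, r), so a single foreground pixel yields a 1x1 box.

#' Construct a box tibble
#'
#' Axis-aligned rectangles in continuous pixel coordinates (origin top-left,
#' x rightward, y downward). All four arguments are recycled to a common
#' length, so this builds one row per box.
#'
#' @param xmin,ymin,xmax,ymax Box extents; must satisfy `xmin <= xmax`,
#'   `ymin <= ymax` and be finite.
#' @return A tibble with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
#' @examples
#' boxes(0, 0, c(4, 8), c(4, 6))
boxes <- function(xmin, ymin, xmax, ymax) {
  out <- tibble(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_boxes(out)
}

validate_boxes <- function(b) {
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(b))) {
    abort("a box tibble needs columns xmin, ymin, xmax, ymax")
  }
  vals <- unlist(b[need])
  if (length(vals) && !all(is.finite(vals))) abort("box coordinates must be finite")
  if (any(b$xmin > b$xmax) || any(b$ymin > b$ymax)) {
    abort("boxes must satisfy xmin <= xmax and ymin <= ymax")
  }
  b
}

box_area <- function(b) (b$xmax - b$xmin) * (b$ymax - b$ymin)

#' Tight boxes around connected components of a binary mask
#'
#' Labels the foreground of a binary mask into connected components and
#' returns, per component, the tight axis-aligned box spanning the minimum
#' and maximum foreground pixel coordinates. Components are numbered in
#' row-major order of their first foreground pixel.
#'
#' @param mask A binary matrix (0/1, logical, or 0/255).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8: diagonal
#'   touching counts, appropriate for blob-like structures).
#' @return A tibble with columns `instance`, `xmin`, `ymin`, `xmax`, `ymax`.
#'   An all-background mask yields zero rows.
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 3:5] <- 1L
#' mask_to_boxes(m)
mask_to_boxes <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) abort("`mask` must be a 2D matrix")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1, 255, FALSE, TRUE))) {
    abort("`mask` must be binary (0/1, logical, or 0/255)")
  }
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- cpp_label_components(m, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) {
    return(tibble(instance = integer(), xmin = numeric(), ymin = numeric(),
                  xmax = numeric(), ymax = numeric()))
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    out[[i]] <- tibble(
      instance = i,
      xmin = as.numeric(min(idx[, 2L]) - 1L),
      ymin = as.numeric(min(idx[, 1L]) - 1L),
      xmax = as.numeric(max(idx[, 2L])),
      ymax = as.numeric(max(idx[, 1L]))
    )
  }
  dplyr::bind_rows(out)
}

#' Intersection-over-union and distance-IoU between boxes
#'
#' `box_iou()` is the standard Jaccard overlap of two axis-aligned boxes.
#' `diou()` penalizes IoU by the squared distance between box centres,
#' normalized by the squared diagonal of the smallest enclosing box:
#' `DIoU = IoU - d^2 / c^2`. It is symmetric, never exceeds IoU, and equals
#' IoU exactly when the centres coincide. Zero-area boxes contribute IoU 0;
#' two zero-area boxes at the same point score 0.
#'
#' Both functions vectorize rowwise over two box tibbles (recycling a
#' single-row argument).
#'
#' @param a,b Box tibbles (see [boxes()]).
#' @return A numeric vector of scores; `diou()` lies in (-1, 1].
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  iw <- pmax(0, pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin))
  ih <- pmax(0, pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin))
  inter <- iw * ih
  uni <- box_area(a) + box_area(b) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' @rdname box_iou
#' @export
diou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  iou <- box_iou(a, b)
  dx <- (a$xmin + a$xmax) / 2 - (b$xmin + b$xmax) / 2
  dy <- (a$ymin + a$ymax) / 2 - (b$ymin + b$ymax) / 2
  d2 <- dx * dx + dy * dy
  cw <- pmax(a$xmax, b$xmax) - pmin(a$xmin, b$xmin)
  ch <- pmax(a$ymax, b$ymax) - pmin(a$ymin, b$ymin)
  c2 <- cw * cw + ch * ch
  ifelse(c2 > 0, iou - d2 / c2, 0)
}

# Numeric core used in training loops: `a`, `b` are n x 4 matrices with
# columns (xmin, ymin, xmax, ymax); rowwise DIoU without tibble overhead.
diou_num <- function(a, b) {
  iw <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  ih <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  inter <- iw * ih
  uni <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L]) +
    (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L]) - inter
  iou <- ifelse(uni > 0, inter / uni, 0)
  dx <- (a[, 1L] + a[, 3L] - b[, 1L] - b[, 3L]) / 2
  dy <- (a[, 2L] + a[, 4L] - b[, 2L] - b[, 4L]) / 2
  cw <- pmax(a[, 3L], b[, 3L]) - pmin(a[, 1L], b[, 1L])
  ch <- pmax(a[, 4L], b[, 4L]) - pmin(a[, 2L], b[, 2L])
  c2 <- cw * cw + ch * ch
  ifelse(c2 > 0, iou - (dx * dx + dy * dy) / c2, 0)
}

box_matrix <- function(b) {
  cbind(xmin = b$xmin, ymin = b$ymin, xmax = b$xmax, ymax = b$ymax)
}

# All-pairs DIoU: rows of `a` (n) against rows of `b` (m) -> n x m matrix.
diou_matrix <- function(a, b) {
  am <- if (is.matrix(a)) a else box_matrix(a)
  bm <- if (is.matrix(b)) b else box_matrix(b)
  n <- nrow(am); m <- nrow(bm)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    out[, j] <- diou_num(am, bm[rep(j, n), , drop = FALSE])
  }
  out
}

#' Anchor points of a feature grid
#'
#' One anchor per feature cell, at the cell centre in image coordinates.
#'
#' @param h,w Feature-map height and width (cells).
#' @param stride Pixels per feature cell (one of 8, 16, 32).
#' @return A tibble with columns `cx`, `cy`, `stride`, ordered column-major
#'   to match flattened feature maps.
#' @export
anchor_grid <- function(h, w, stride) {
  if (!stride %in% c(8, 16, 32)) abort("`stride` must be 8, 16 or 32")
  tibble(
    cx = rep((seq_len(w) - 0.5) * stride, each = h),
    cy = rep((seq_len(h) - 0.5) * stride, times = w),
    stride = stride
  )
}

#' Decode per-edge bin distributions into a box
#'
#' The distance from an anchor centre to each box side (top, bottom, left,
#' right) is represented as a categorical distribution over `B` discrete
#' spatial bins of width `bin_width` pixels. Decoding takes the expectation
#' over bin indices under the softmax of the logits (temperature 1):
#' `d_e = sum_i softmax(z_e)_i * i * bin_width`, with bin index `i` starting
#' at 0. The decoded box is
#' `(cx - d_l, cy - d_t, cx + d_r, cy + d_b)`; distances are nonnegative by
#' construction, so the box is always valid.
#'
#' @param logits A 4 x B numeric matrix of edge logits, rows ordered
#'   top, bottom, left, right (a list of four equal-length vectors is also
#'   accepted; unequal lengths are rejected).
#' @param anchor A one-row tibble or list with `cx`, `cy` (see
#'   [anchor_grid()]).
#' @param bin_width Pixels per bin; defaults to `anchor$stride`.
#' @return A one-row box tibble.
#' @export
decode_edges <- function(logits, anchor, bin_width = NULL) {
  if (is.list(logits) && !is.matrix(logits)) {
    lens <- lengths(logits)
    if (length(logits) != 4L || length(unique(lens)) != 1L) {
      abort("edge distributions must share a common number of bins")
    }
    logits <- do.call(rbind, logits)
  }
  if (!is.matrix(logits) || nrow(logits) != 4L || ncol(logits) < 2L) {
    abort("`logits` must be a 4 x B matrix with B >= 2")
  }
  if (is.null(bin_width)) bin_width <- anchor$stride
  B <- ncol(logits)
  p <- t(apply(logits, 1L, function(z) generalized_softmax(z, 1)))
  d <- as.numeric(p %*% (seq_len(B) - 1)) * bin_width   # t, b, l, r
  boxes(anchor$cx - d[3L], anchor$cy - d[1L],
        anchor$cx + d[4L], anchor$cy + d[2L])
}
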