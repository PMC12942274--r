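# Synthetic scenes for the regime the method targets: low foreground /
# background contrast, boundaries genuinely ambiguous after Gaussian
# blurring, additive noise, and 1-3 (possibly touching) deformable
# instances per image.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Scene configuration for the synthetic generator
#'
#' @param image_size Side length in pixels (square images; default 64).
#' @param n_instances Integer range `c(min, max)` of instances per image
#'   (default 1 to 3).
#' @param shape_families Families sampled per instance: any of
#'   `"ellipse"`, `"perturbed-polygon"`, `"smoothed-blob"`.
#' @param fg_mean,bg_mean Foreground / background intensity means in
#'   `[0, 1]` (defaults 0.65 / 0.35 - deliberately low contrast).
#' @param noise_sd Additive Gaussian noise standard deviation
#'   (default 0.10).
#' @param blur_sigma Gaussian boundary-blur radius in pixels, applied
#'   before the noise so edges are ambiguous (default 1.5).
#' @param seed Mandatory integer seed; generation is fully deterministic
#'   given the configuration.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_size = 64L, n_instances = c(1L, 3L),
                         shape_families = c("ellipse", "perturbed-polygon",
                                            "smoothed-blob"),
                         fg_mean = 0.65, bg_mean = 0.35,
                         noise_sd = 0.10, blur_sigma = 1.5, seed) {
  if (missing(seed)) abort("`seed` is mandatory in scene_config()")
  if (fg_mean < 0 || fg_mean > 1 || bg_mean < 0 || bg_mean > 1) {
    abort("intensity means must lie in [0, 1]")
  }
  if (n_instances[1L] < 1L) abort("at least one instance per image")
  shape_families <- match.arg(shape_families, several.ok = TRUE)
  structure(
    list(image_size = as.integer(image_size),
         n_instances = as.integer(n_instances),
         shape_families = shape_families, fg_mean = fg_mean,
         bg_mean = bg_mean, noise_sd = noise_sd, blur_sigma = blur_sigma,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Rasterize one random instance mask on an n x n grid. All shapes are
# star-shaped around their centre, so a pixel is foreground iff its
# distance from the centre is below the boundary radius at its angle.
random_instance_mask <- function(n, family) {
  cx <- stats::runif(1, 0.18, 0.82) * n
  cy <- stats::runif(1, 0.18, 0.82) * n
  r0 <- stats::runif(1, 0.09, 0.20) * n
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)   # pixel-centre x
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)  # pixel-centre y
  dx <- xs - cx; dy <- ys - cy
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  rb <- switch(
    family,
    "ellipse" = {
      a <- r0 * stats::runif(1, 0.9, 1.3)
      b <- r0 * stats::runif(1, 0.6, 1.0)
      th <- stats::runif(1, 0, pi)
      co <- cos(phi - th); si <- sin(phi - th)
      a * b / sqrt((b * co)^2 + (a * si)^2)
    },
    "smoothed-blob" = {
      amp <- stats::runif(3, 0, 0.22) / (1:3)
      ph <- stats::runif(3, 0, 2 * pi)
      mod <- 1 + amp[1] * cos(2 * phi + ph[1]) +
        amp[2] * cos(3 * phi + ph[2]) + amp[3] * cos(4 * phi + ph[3])
      r0 * pmax(mod, 0.4)
    },
    "perturbed-polygon" = {
      m <- sample(5:8, 1)
      va <- sort(stats::runif(m, 0, 2 * pi))
      vr <- r0 * stats::runif(m, 0.75, 1.25)
      # polar equation of the chord between consecutive vertices
      rbm <- matrix(Inf, n, n)
      for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        a1 <- va[i]; a2 <- if (j == 1L) va[j] + 2 * pi else va[j]
        ph2 <- phi
        ph2[ph2 < a1 - pi] <- ph2[ph2 < a1 - pi] + 2 * pi
        sel <- ph2 >= a1 & ph2 < a2
        denom <- vr[j] * sin(a2 - ph2) + vr[i] * sin(ph2 - a1)
        rr <- vr[i] * vr[j] * sin(a2 - a1) / pmax(denom, 1e-9)
        rbm[sel] <- rr[sel]
      }
      rbm
    }
  )
  mask <- matrix(as.integer(d <= rb), n, n)
  mask
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  # reflect-pad then shift-and-add along each axis
  pad_idx <- function(len) c(rev(seq_len(hw)), seq_len(len), len + 1 - seq_len(hw))
  xp <- x[pad_idx(n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(k)) out <- out + k[t] * xp[(t - 1) + seq_len(n), , drop = FALSE]
  xp <- out[, pad_idx(m), drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(k)) out <- out + k[t] * xp[, (t - 1) + seq_len(m), drop = FALSE]
  out
}

#' Generate a synthetic segmentation dataset
#'
#' Draws `n` scenes under a [scene_config()]: deformable instance masks
#' (ellipses, perturbed star polygons, smoothed blobs), a low-contrast
#' intensity image composited from the foreground/background means, a
#' Gaussian boundary blur applied *before* additive noise, and tight boxes
#' derived from each instance mask via [mask_to_boxes()]. Instances may
#' touch or partially overlap; an instance is retried (bounded) if nearly
#' all of it would be hidden by earlier ones.
#'
#' @param cfg A [scene_config()].
#' @param n Number of samples (>= 1).
#' @return A list of `seg_sample` objects, each a list with `id`, `image`
#'   (matrix in `[0, 1]`), `masks` (per-instance binary matrices),
#'   `union_mask`, and `boxes` (a box tibble with one row per instance).
#' @export
generate_dataset <- function(cfg, n) {
  stopifnot(inherits(cfg, "scene_config"), n >= 1)
  with_seed(cfg$seed, {
    lapply(seq_len(n), function(i) generate_sample(cfg, sprintf("s%05d", i)))
  })
}

generate_sample <- function(cfg, id) {
  sz <- cfg$image_size
  k <- if (cfg$n_instances[1L] == cfg$n_instances[2L]) cfg$n_instances[1L] else
    sample(cfg$n_instances[1L]:cfg$n_instances[2L], 1L)
  masks <- list()
  covered <- matrix(0L, sz, sz)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in 1:20) {
      fam <- sample(cfg$shape_families, 1L)
      m <- random_instance_mask(sz, fam)
      visible <- sum(m == 1L & covered == 0L)
      if (sum(m) >= 12L && visible >= 0.5 * sum(m)) { ok <- TRUE; break }
    }
    if (!ok) {
      if (length(masks) == 0L && j == k) {
        abort("could not place any instance under this scene configuration")
      }
      next
    }
    masks[[length(masks) + 1L]] <- m
    covered <- pmax(covered, m)
  }
  if (length(masks) == 0L) {
    abort("could not place any instance under this scene configuration")
  }
  img <- matrix(cfg$bg_mean, sz, sz)
  for (m in masks) img[m == 1L] <- cfg$fg_mean
  img <- gaussian_blur(img, cfg$blur_sigma)
  if (cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(sz * sz, sd = cfg$noise_sd), sz, sz)
  }
  img <- pmin(pmax(img, 0), 1)
  union_mask <- covered
  bx <- dplyr::bind_rows(lapply(seq_along(masks), function(j) {
    b <- mask_to_boxes(masks[[j]])
    # one drawn instance can only be a single component per construction,
    # but clipping at the border may split it: take the spanning box.
    tibble(instance = j, xmin = min(b$xmin), ymin = min(b$ymin),
           xmax = max(b$xmax), ymax = max(b$ymax))
  }))
  structure(
    list(id = id, image = img, masks = masks, union_mask = union_mask,
         boxes = bx),
    class = "seg_sample"
  )
}

#' Deterministic dataset split
#'
#' Sample ids are sorted lexicographically and subjected to a single
#' shuffle with the seeded generator; the first `ceiling(test_frac * n)`
#' ids form the test set, the next `ceiling(val_frac * n)` the validation
#' set, and the remainder the training set. The partitions are disjoint
#' and exhaustive, and identical across runs for a fixed seed.
#'
#' @param samples A list of `seg_sample` objects.
#' @param test_frac,val_frac Holdout fractions in (0, 1) with
#'   `test_frac + val_frac < 1`.
#' @param seed Shuffle seed (default 2025).
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, test_frac = 0.2, val_frac = 0.1,
                          seed = 2025L) {
  if (test_frac <= 0 || val_frac <= 0 || test_frac + val_frac >= 1) {
    abort("holdout fractions must be in (0,1) and sum below 1")
  }
  ids <- vapply(samples, function(s) s$id, character(1))
  if (anyDuplicated(ids)) abort("sample ids must be unique")
  n <- length(ids)
  n_test <- ceiling(test_frac * n)
  n_val <- ceiling(val_frac * n)
  if (n_test + n_val >= n) abort("too few samples for nonempty splits")
  ord <- with_seed(seed, sample(sort(ids)))
  test_ids <- ord[seq_len(n_test)]
  val_ids <- ord[n_test + seq_len(n_val)]
  train_ids <- ord[(n_test + n_val + 1):n]
  pick <- function(which_ids) samples[match(which_ids, ids)]
  list(train = pick(train_ids), val = pick(val_ids), test = pick(test_ids))
}

#' Nested annotation-budget subsets
#'
#' Returns the first `ceiling(fraction * n)` training samples of a seeded
#' shuffle of the lexicographically sorted ids. Because every budget reads
#' a prefix of the *same* shuffle, subsets are nested
#' (10% within 20% within 50% within 100%), and the identical subset feeds
#' both the distillation boxes and the segmentation masks (supervision
#' parity across training stages).
#'
#' @param samples Training samples (list of `seg_sample`).
#' @param fraction Budget fraction in (0, 1]; the canonical grid is
#'   0.1, 0.2, 0.5, 1.0.
#' @param seed Shuffle seed (default 2025).
#' @return A list of `seg_sample` objects.
#' @export
budget_subset <- function(samples, fraction, seed = 2025L) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1]")
  ids <- vapply(samples, function(s) s$id, character(1))
  ord <- with_seed(seed, sample(sort(ids)))
  keep <- ord[seq_len(ceiling(fraction * length(ids)))]
  samples[match(keep, ids)]
}
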