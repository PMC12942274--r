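# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny deterministic dataset for pipeline tests.
tiny_dataset <- function(n = 12, seed = 11) {
  generate_dataset(scene_config(seed = seed), n)
}

# Random valid boxes inside a `size` x `size` frame.
random_boxes <- function(n, size = 64, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- runif(n, 0, size - 2)
  y1 <- runif(n, 0, size - 2)
  boxes(x1, y1, x1 + runif(n, 0.5, size / 2), y1 + runif(n, 0.5, size / 2))
}

# Random binary blob-ish mask.
random_mask <- function(h = 16, w = 16, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w)
}

# Brute-force oracle: per-component min/max scan over foreground pixels,
# with its own tiny flood fill (independent of the package's C++ path).
brute_mask_boxes <- function(mask, connectivity = 8) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      for (d in seq_len(nrow(nb))) {
        ni <- q[1L] + nb[d, 1L]; nj <- q[2L] + nb[d, 2L]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- k
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(instance = integer(), xmin = numeric(),
                          ymin = numeric(), xmax = numeric(),
                          ymax = numeric()))
  }
  dplyr::bind_rows(lapply(seq_len(k), function(cc) {
    px <- which(lab == cc, arr.ind = TRUE)
    tibble::tibble(instance = cc, xmin = min(px[, 2]) - 1,
                   ymin = min(px[, 1]) - 1, xmax = max(px[, 2]),
                   ymax = max(px[, 1]))
  }))
}

# Finite-difference gradient of a scalar-valued builder with respect to
# one element of parameter node `p`.
fd_grad <- function(build, p, idx, h = 1e-6) {
  v0 <- p$value[matrix(idx, 1)]
  p$value[matrix(idx, 1)] <- v0 + h
  lp <- ldseg:::ag_value(build())
  p$value[matrix(idx, 1)] <- v0 - h
  lm <- ldseg:::ag_value(build())
  p$value[matrix(idx, 1)] <- v0
  (lp - lm) / (2 * h)
}

analytic_grad <- function(build, params, p, idx) {
  for (q in params) q$grad <- NULL
  l <- build()
  ldseg:::ag_backward(l)
  g <- p$grad[matrix(idx, 1)]
  for (q in params) q$grad <- NULL
  g
}
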