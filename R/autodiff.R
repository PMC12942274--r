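#' @useDynLib ldseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# Every differentiable quantity is a node: an environment holding `value`
# (a numeric vector/matrix/array), `grad` (accumulated during backward),
# `parents` (list of upstream nodes) and `backward` (a function taking the
# gradient at this node and returning one gradient per parent). Graphs are
# rebuilt on every forward pass; parameters (`ag_param`) are persistent leaf
# nodes whose `grad` accumulates across backward calls until `ag_zero_grad`.
#
# The op set is exactly what the miniature models need: convolutions
# (via im2col/col2im in src/), transposed convolutions, bilinear resampling,
# SiLU, linear layers, matrix products, row softmax, slicing/concatenation,
# and a `ag_custom` escape hatch for losses whose gradient is supplied
# analytically. Correctness is established by finite-difference checks in
# the test suite.
# ---------------------------------------------------------------------------

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_new <- function(value, parents = list(), backward = NULL,
                   param = FALSE, trainable = FALSE) {
  # Force all arguments *before* drawing an id: argument promises may
  # themselves construct nodes, and the id must be unique and drawn last.
  force(value); force(parents); force(backward)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$trainable <- trainable
  .ag_counter$n <- .ag_counter$n + 1L
  node$id <- .ag_counter$n
  class(node) <- "ag_node"
  node
}

is_ag <- function(x) inherits(x, "ag_node")

#' @noRd
ag_input <- function(value) ag_new(value)

#' @noRd
ag_param <- function(value, trainable = TRUE) {
  ag_new(value, param = TRUE, trainable = trainable)
}

ag_value <- function(x) if (is_ag(x)) x$value else x

# Coerce plain numerics to constant leaves so ops compose freely.
as_ag <- function(x) if (is_ag(x)) x else ag_input(x)

#' Run backward from a scalar node, accumulating gradients into leaves.
#'
#' Reverse DFS postorder gives a topological order of the graph; gradients
#' flow from the root towards the leaves, summing over consumers.
#' Visitation is tracked by a per-call token written into each node, and
#' gradients live in a list indexed by the node's position in the order,
#' so no per-node hashing is needed.
#' @noRd
ag_backward <- function(root, seed_grad = 1) {
  stopifnot(is_ag(root))
  .ag_counter$token <- (.ag_counter$token %||% 0L) + 1L
  token <- .ag_counter$token
  cap <- 512L
  stack <- vector("list", cap)
  stage <- integer(cap)
  order <- vector("list", cap)
  n_ord <- 0L
  top <- 1L
  stack[[1L]] <- root
  stage[1L] <- 1L
  while (top > 0L) {
    node <- stack[[top]]
    if (stage[top] == 1L) {
      if (identical(node$.seen, token)) { top <- top - 1L; next }
      node$.seen <- token
      stage[top] <- 2L
      for (p in node$parents) {
        if (!identical(p$.seen, token)) {
          top <- top + 1L
          if (top > cap) {
            cap <- cap * 2L
            length(stack) <- cap
            length(stage) <- cap
          }
          stack[[top]] <- p
          stage[top] <- 1L
        }
      }
    } else {
      top <- top - 1L
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) length(order) <- 2L * length(order)
      order[[n_ord]] <- node
      node$.bidx <- n_ord
    }
  }
  grads <- vector("list", n_ord)
  grads[[root$.bidx]] <- seed_grad
  for (i in n_ord:1L) {
    node <- order[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (node$param) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
    }
    if (!is.null(node$backward)) {
      pg <- node$backward(g)
      parents <- node$parents
      for (j in seq_along(parents)) {
        if (is.null(pg[[j]])) next
        bi <- parents[[j]]$.bidx
        old <- grads[[bi]]
        grads[[bi]] <- if (is.null(old)) pg[[j]] else old + pg[[j]]
      }
    }
    grads[i] <- list(NULL)
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# --- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul_const <- function(x, k) {
  ag_new(x$value * k, list(x), function(g) list(g * k))
}

# x scaled by a *learnable scalar* node s (the dense-prompt gate).
ag_scale <- function(x, s) {
  xv <- x$value; sv <- as.numeric(s$value)
  ag_new(xv * sv, list(x, s),
         function(g) list(g * sv, sum(g * xv)))
}

ag_add_bias <- function(x, b) {
  # x: (H, W, C) array, b: length-C vector
  d <- dim(x$value)
  bv <- rep(b$value, each = d[1L] * d[2L])
  ag_new(x$value + bv, list(x, b), function(g) {
    list(g, colSums(matrix(g, d[1L] * d[2L], d[3L])))
  })
}

ag_silu <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  ag_new(xv * s, list(x), function(g) list(g * (s * (1 + xv * (1 - s)))))
}

ag_sum_nodes <- function(nodes) {
  vals <- vapply(nodes, function(n) as.numeric(n$value), numeric(1))
  ag_new(sum(vals), nodes, function(g) rep(list(g), length(nodes)))
}

# --- shape ----------------------------------------------------------------

ag_reshape <- function(x, dims) {
  od <- dim(x$value) %||% length(x$value)
  v <- x$value
  dim(v) <- dims
  ag_new(v, list(x), function(g) { dim(g) <- od; list(g) })
}

ag_rows <- function(x, idx) {
  v <- x$value[idx, , drop = FALSE]
  ag_new(v, list(x), function(g) {
    out <- array(0, dim(x$value))
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

ag_cols <- function(x, idx) {
  v <- x$value[, idx, drop = FALSE]
  ag_new(v, list(x), function(g) {
    out <- array(0, dim(x$value))
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

ag_concat_rows <- function(xs) {
  vals <- lapply(xs, ag_value)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_new(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ag_concat_cols <- function(xs) {
  vals <- lapply(xs, ag_value)
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_new(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_concat_channels <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1L]])
  nch <- vapply(vals, function(v) dim(v)[3L], numeric(1))
  ends <- cumsum(nch)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- array(0, c(d1[1L], d1[2L], sum(nch)))
  for (i in seq_along(vals)) out[, , starts[i]:ends[i]] <- vals[[i]]
  ag_new(out, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , starts[i]:ends[i], drop = FALSE])
  })
}

# --- linear algebra -------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_new(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ag_transpose <- function(x) {
  ag_new(t(x$value), list(x), function(g) list(t(g)))
}

# X (m x n) %*% W (n x p) + bias (p)
ag_linear <- function(x, w, b = NULL) {
  xv <- x$value
  if (is.null(dim(xv))) xv <- matrix(xv, nrow = 1L)
  wv <- w$value
  out <- xv %*% wv
  if (!is.null(b)) out <- sweep(out, 2L, b$value, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_new(out, parents, function(g) {
    gx <- g %*% t(wv)
    if (is.null(dim(x$value))) gx <- as.numeric(gx)
    out <- list(gx, t(xv) %*% g)
    if (!is.null(b)) out <- c(out, list(colSums(g)))
    out
  })
}

ag_softmax_rows <- function(x) {
  v <- x$value
  m <- v - apply(v, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_new(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# --- convolution ----------------------------------------------------------

# x: (H, W, Cin); w: (kh, kw, Cin, Cout); b: length Cout; zero padding.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 1L) {
  xv <- x$value
  d <- dim(xv)
  wd <- dim(w$value)
  stopifnot(d[3L] == wd[3L])
  ho <- (d[1L] + 2L * pad - wd[1L]) %/% stride + 1L
  wo <- (d[2L] + 2L * pad - wd[2L]) %/% stride + 1L
  xcol <- cpp_im2col(as.numeric(xv), d[1L], d[2L], d[3L],
                     wd[1L], wd[2L], as.integer(stride), as.integer(pad))
  wmat <- matrix(w$value, nrow = wd[1L] * wd[2L] * wd[3L], ncol = wd[4L])
  y <- xcol %*% wmat
  if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
  dim(y) <- c(ho, wo, wd[4L])
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_new(y, parents, function(g) {
    gmat <- matrix(g, nrow = ho * wo, ncol = wd[4L])
    gx <- cpp_col2im(gmat %*% t(wmat), d[1L], d[2L], d[3L],
                     wd[1L], wd[2L], as.integer(stride), as.integer(pad))
    gw <- t(xcol) %*% gmat
    dim(gw) <- wd
    out <- list(gx, gw)
    if (!is.null(b)) out <- c(out, list(colSums(gmat)))
    out
  })
}

# Transposed convolution: the adjoint of ag_conv2d with the same kernel
# layout. Maps (h, w, Cout) -> (out_h, out_w, Cin) where
# h == (out_h + 2*pad - kh) %/% stride + 1.
ag_convT2d <- function(x, w, b = NULL, stride = 2L, pad = 0L,
                       out_h = NULL, out_w = NULL) {
  xv <- x$value
  d <- dim(xv)
  wd <- dim(w$value)       # (kh, kw, Cin, Cout); output has Cin channels
  stopifnot(d[3L] == wd[4L])
  if (is.null(out_h)) out_h <- (d[1L] - 1L) * stride + wd[1L] - 2L * pad
  if (is.null(out_w)) out_w <- (d[2L] - 1L) * stride + wd[2L] - 2L * pad
  stopifnot((out_h + 2L * pad - wd[1L]) %/% stride + 1L == d[1L])
  wmat <- matrix(w$value, nrow = wd[1L] * wd[2L] * wd[3L], ncol = wd[4L])
  xmat <- matrix(xv, nrow = d[1L] * d[2L], ncol = d[3L])
  y <- cpp_col2im(xmat %*% t(wmat), out_h, out_w, wd[3L],
                  wd[1L], wd[2L], as.integer(stride), as.integer(pad))
  if (!is.null(b)) {
    y <- y + rep(b$value, each = out_h * out_w)
    dim(y) <- c(out_h, out_w, wd[3L])
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_new(y, parents, function(g) {
    gcol <- cpp_im2col(as.numeric(g), out_h, out_w, wd[3L],
                       wd[1L], wd[2L], as.integer(stride), as.integer(pad))
    gx <- gcol %*% wmat
    dim(gx) <- d
    gw <- t(gcol) %*% xmat
    dim(gw) <- wd
    out <- list(gx, gw)
    if (!is.null(b)) out <- c(out, list(colSums(matrix(g, out_h * out_w, wd[3L]))))
    out
  })
}

# --- resampling -----------------------------------------------------------

# Bilinear interpolation weights from `n_in` samples to `n_out`
# (corner-aligned sampling off, i.e. half-pixel centres).
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5      # 0-based source coordinate
    i0 <- floor(src)
    f <- src - i0
    lo <- min(max(i0, 0), n_in - 1) + 1
    hi <- min(max(i0 + 1, 0), n_in - 1) + 1
    W[i, lo] <- W[i, lo] + (1 - f)
    W[i, hi] <- W[i, hi] + f
  }
  W
}

ag_resize_bilinear <- function(x, out_h, out_w) {
  xv <- x$value
  d <- dim(xv)
  Wr <- bilinear_weights(d[1L], out_h)
  Wc <- bilinear_weights(d[2L], out_w)
  out <- array(0, c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L])) out[, , c] <- Wr %*% xv[, , c] %*% t(Wc)
  ag_new(out, list(x), function(g) {
    gx <- array(0, d)
    for (c in seq_len(d[3L])) gx[, , c] <- t(Wr) %*% g[, , c] %*% Wc
    list(gx)
  })
}

# Global average pool (H, W, C) -> length-C vector.
ag_gap <- function(x) {
  d <- dim(x$value)
  n <- d[1L] * d[2L]
  v <- colMeans(matrix(x$value, n, d[3L]))
  ag_new(v, list(x), function(g) {
    gx <- rep(g / n, each = n)
    dim(gx) <- d
    list(gx)
  })
}

# --- custom loss node -----------------------------------------------------

# A scalar node whose value and gradient w.r.t. `x$value` were computed
# analytically by the caller (used for detection / distillation losses).
ag_custom <- function(x, value, grad_x) {
  force(grad_x)
  ag_new(value, list(x), function(g) list(g * grad_x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
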