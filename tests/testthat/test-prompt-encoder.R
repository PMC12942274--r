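# Direct convolution oracle: plain R loops, zero padding.
conv_oracle <- function(x, w, b, stride = 1L, pad = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ho <- (H + 2 * pad - kh) %/% stride + 1
  wo <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  out <- array(0, c(ho, wo, cout))
  for (oc in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- b[oc]
    for (c in seq_len(cin)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      acc <- acc + xp[(i - 1) * stride + ki, (j - 1) * stride + kj, c] *
        w[ki, kj, c, oc]
    }
    out[i, j, oc] <- acc
  }
  out
}

make_pyramid <- function(h, ch, fill = NULL, seed = 1) {
  set.seed(seed)
  gen <- function(n, c) {
    if (is.null(fill)) array(rnorm(n * n * c), c(n, n, c))
    else array(fill, c(n, n, c))
  }
  list(P3 = gen(h, ch), P4 = gen(h / 2, ch), P5 = gen(h / 4, ch))
}

test_that("fuse_pyramid meets the stride-8 resolution contract", {
  spec <- model_spec()
  set.seed(41)
  pe <- new_prompt_encoder(spec)
  ch <- 2L * spec$student_width
  for (h in c(4, 8, 16)) {
    f <- fuse_pyramid(pe, make_pyramid(h, ch))
    expect_equal(dim(ldseg:::ag_value(f)), c(h, h, spec$fused_channels))
  }
  # all-zero pyramid with zero biases -> all-zero output (linearity)
  f0 <- fuse_pyramid(pe, make_pyramid(8, ch, fill = 0))
  expect_equal(max(abs(ldseg:::ag_value(f0))), 0)
  # inconsistent pyramid dims are rejected
  bad <- make_pyramid(8, ch); bad$P4 <- bad$P5
  expect_error(fuse_pyramid(pe, bad), "halve")
})

test_that("the mixing block matches a direct convolution oracle", {
  spec <- model_spec()
  set.seed(42)
  pe <- new_prompt_encoder(spec)
  ch <- 2L * spec$student_width
  pyr <- make_pyramid(8, ch, seed = 5)
  f <- ldseg:::ag_value(fuse_pyramid(pe, pyr))
  # reproduce: bilinear upsample -> concat -> 1x1 conv -> SiLU -> 3x3 -> SiLU
  up <- function(x, n) {
    Wr <- ldseg:::bilinear_weights(dim(x)[1], n)
    out <- array(0, c(n, n, dim(x)[3]))
    for (c in seq_len(dim(x)[3])) out[, , c] <- Wr %*% x[, , c] %*% t(Wr)
    out
  }
  cc <- array(0, c(8, 8, 3 * ch))
  cc[, , seq_len(ch)] <- pyr$P3
  cc[, , ch + seq_len(ch)] <- up(pyr$P4, 8)
  cc[, , 2 * ch + seq_len(ch)] <- up(pyr$P5, 8)
  silu <- function(x) x / (1 + exp(-x))
  h1 <- silu(conv_oracle(cc, pe$mix1$w$value, pe$mix1$b$value, pad = 0))
  h2 <- silu(conv_oracle(h1, pe$mix3$w$value, pe$mix3$b$value, pad = 1))
  expect_equal(f, h2, tolerance = 1e-10)
})

test_that("dense_prompt halves resolution to the embedding grid", {
  spec <- model_spec()
  set.seed(43)
  pe <- new_prompt_encoder(spec)
  for (h in c(16, 32, 64)) {
    x <- array(rnorm(h * h * spec$fused_channels),
               c(h, h, spec$fused_channels))
    d <- ldseg:::ag_value(dense_prompt(pe, x))
    expect_equal(dim(d), c(h / 2, h / 2, spec$embed_dim))
  }
  # zero input, zero bias -> zero output
  x0 <- array(0, c(16, 16, spec$fused_channels))
  expect_equal(max(abs(ldseg:::ag_value(dense_prompt(pe, x0)))), 0)
  # toy strided convolution against the direct oracle
  x <- array(rnorm(6 * 6 * spec$fused_channels), c(6, 6, spec$fused_channels))
  got <- ldseg:::ag_value(dense_prompt(pe, x))
  want <- conv_oracle(x, pe$dense_head$w$value, pe$dense_head$b$value,
                      stride = 2, pad = 1)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("inject_dense is the alpha-gated residual of the formulation", {
  set.seed(44)
  z <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  p <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  # alpha = 0: bit-identical to the input embedding (initialization)
  expect_identical(ldseg:::ag_value(inject_dense(z, p, 0)), z)
  # zero prompt: identity for any alpha
  expect_equal(ldseg:::ag_value(inject_dense(z, p * 0, 1.7)), z)
  # elementwise oracle at alpha = 0.5
  expect_equal(ldseg:::ag_value(inject_dense(z, p, 0.5)), z + 0.5 * p)
  # linear in alpha on a 3-point grid
  v <- vapply(c(0.2, 0.5, 0.8), function(a)
    ldseg:::ag_value(inject_dense(z, p, a))[2, 3, 4], numeric(1))
  expect_equal(v[2], mean(v[c(1, 3)]), tolerance = 1e-12)
  expect_error(inject_dense(z, p[, , 1:4], 1), "identical shapes")
})

test_that("sparse_prompt pools globally and emits K tokens", {
  spec <- model_spec()
  set.seed(45)
  pe <- new_prompt_encoder(spec)
  x <- array(rnorm(8 * 8 * spec$fused_channels), c(8, 8, spec$fused_channels))
  tok <- ldseg:::ag_value(sparse_prompt(pe, x))
  expect_equal(dim(tok), c(4L, spec$embed_dim))   # K = 4 by default

  # GAP equals direct per-channel means
  g <- ldseg:::ag_value(ldseg:::ag_gap(ldseg:::ag_input(x)))
  expect_equal(g, apply(x, 3, mean), tolerance = 1e-9)
  # spatially constant map: GAP returns the constant channel vector
  v <- rnorm(spec$fused_channels)
  xc <- array(rep(v, each = 64), c(8, 8, spec$fused_channels))
  expect_equal(ldseg:::ag_value(ldseg:::ag_gap(ldseg:::ag_input(xc))), v,
               tolerance = 1e-12)

  # K is configurable
  pe2 <- new_prompt_encoder(model_spec(n_sparse = 2L))
  expect_equal(nrow(ldseg:::ag_value(sparse_prompt(pe2, x))), 2L)
})

test_that("box prompt tokens are deterministic sinusoidal encodings", {
  spec <- model_spec()
  set.seed(46)
  pe <- new_prompt_encoder(spec)
  b <- boxes(8, 12, 40, 52)
  t1 <- ldseg:::ag_value(box_prompt_tokens(pe, b))
  t2 <- ldseg:::ag_value(box_prompt_tokens(pe, b))
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(2L, spec$embed_dim))

  # direct sin/cos evaluation oracle for the first corner
  d <- spec$embed_dim
  nf <- d %/% 4
  freqs <- 2 * pi * 2^(seq_len(nf) - 1)
  want <- c(sin(freqs * 8 / 64), cos(freqs * 8 / 64),
            sin(freqs * 12 / 64), cos(freqs * 12 / 64))
  expect_equal(t1[1, ], want + pe$corner_embed$value[1, ], tolerance = 1e-12)

  # the two corners share the positional scheme but differ by the learned
  # corner-type embedding
  bsym <- boxes(10, 10, 10, 10)  # degenerate: both corners equal
  ts <- ldseg:::ag_value(box_prompt_tokens(pe, bsym))
  expect_equal(ts[1, ] - pe$corner_embed$value[1, ],
               ts[2, ] - pe$corner_embed$value[2, ], tolerance = 1e-12)

  # out-of-image boxes are clamped with a warning
  expect_warning(box_prompt_tokens(pe, boxes(-5, 0, 70, 64)), "clamp")
})

test_that("the full prompt path is deterministic and additive at init", {
  spec <- model_spec()
  set.seed(47)
  pe <- new_prompt_encoder(spec)
  ch <- 2L * spec$student_width
  pyr <- make_pyramid(8, ch, seed = 9)
  z <- array(rnorm(4 * 4 * spec$embed_dim), c(4, 4, spec$embed_dim))

  bundle <- function() {
    fused <- fuse_pyramid(pe, pyr)
    list(dense = ldseg:::ag_value(dense_prompt(pe, fused)),
         sparse = ldseg:::ag_value(sparse_prompt(pe, fused)),
         cond = ldseg:::ag_value(inject_dense(z, dense_prompt(pe, fused),
                                              pe$alpha)))
  }
  b1 <- bundle(); b2 <- bundle()
  expect_identical(b1, b2)
  # alpha is initialized to exactly 0: conditioning is strictly additive
  expect_identical(as.numeric(pe$alpha$value), 0)
  expect_identical(b1$cond, z)
})
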