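# Layer constructors and the optimizer. A "layer" is a plain list of
# ag_param nodes plus metadata; forward functions live beside them. All
# initialization draws from R's RNG, so model construction is reproducible
# under set.seed().

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_layer <- function(kh, kw, c_in, c_out, trainable = TRUE) {
  list(
    w = ag_param(he_init(c(kh, kw, c_in, c_out), kh * kw * c_in), trainable),
    b = ag_param(numeric(c_out), trainable),
    kh = kh, kw = kw
  )
}

conv_fwd <- function(layer, x, stride = 1L, pad = (layer$kh - 1L) %/% 2L,
                     act = TRUE) {
  out <- ag_conv2d(x, layer$w, layer$b, stride = stride, pad = pad)
  if (act) ag_silu(out) else out
}

convT_layer <- function(kh, kw, c_out, c_in, trainable = TRUE) {
  # kernel layout matches ag_convT2d: (kh, kw, c_out, c_in)
  list(
    w = ag_param(he_init(c(kh, kw, c_out, c_in), kh * kw * c_in), trainable),
    b = ag_param(numeric(c_out), trainable),
    kh = kh, kw = kw
  )
}

convT_fwd <- function(layer, x, stride = 2L, pad = 0L, act = TRUE) {
  out <- ag_convT2d(x, layer$w, layer$b, stride = stride, pad = pad)
  if (act) ag_silu(out) else out
}

linear_layer <- function(n_in, n_out, trainable = TRUE) {
  list(
    w = ag_param(he_init(c(n_in, n_out), n_in), trainable),
    b = ag_param(numeric(n_out), trainable)
  )
}

linear_fwd <- function(layer, x, act = FALSE) {
  out <- ag_linear(x, layer$w, layer$b)
  if (act) ag_silu(out) else out
}

# Scaled dot-product attention block with `heads` heads over dimension d.
attn_layer <- function(d, heads = 2L, trainable = TRUE) {
  stopifnot(d %% heads == 0L)
  list(
    wq = ag_param(he_init(c(d, d), d), trainable),
    wk = ag_param(he_init(c(d, d), d), trainable),
    wv = ag_param(he_init(c(d, d), d), trainable),
    wo = ag_param(he_init(c(d, d), d), trainable),
    d = d, heads = heads
  )
}

attn_fwd <- function(layer, q_in, k_in, v_in) {
  d <- layer$d
  h <- layer$heads
  dh <- d %/% h
  q <- ag_matmul(q_in, layer$wq)
  k <- ag_matmul(k_in, layer$wk)
  v <- ag_matmul(v_in, layer$wv)
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dh + 1L):(i * dh)
    qh <- ag_cols(q, idx)
    kh <- ag_cols(k, idx)
    vh <- ag_cols(v, idx)
    scores <- ag_mul_const(ag_matmul(qh, ag_transpose(kh)), 1 / sqrt(dh))
    outs[[i]] <- ag_matmul(ag_softmax_rows(scores), vh)
  }
  ag_matmul(ag_concat_cols(outs), layer$wo)
}

# --- parameter bookkeeping ------------------------------------------------

# Recursively collect ag_param nodes from nested lists of layers.
collect_params <- function(x) {
  if (is_ag(x)) {
    if (x$param) return(list(x))
    return(list())
  }
  if (is.list(x)) return(unlist(lapply(x, collect_params), recursive = FALSE))
  list()
}

trainable_params <- function(x) {
  Filter(function(p) isTRUE(p$trainable), collect_params(x))
}

n_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}

set_trainable <- function(x, trainable) {
  for (p in collect_params(x)) p$trainable <- trainable
  invisible(x)
}

# Snapshot / compare parameter values (freeze-contract audits).
param_snapshot <- function(x) lapply(collect_params(x), function(p) p$value)

params_identical <- function(snap_a, snap_b) {
  length(snap_a) == length(snap_b) &&
    all(mapply(identical, snap_a, snap_b))
}

# --- Adam -----------------------------------------------------------------

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    params = params,
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0),
    beta1 = beta1, beta2 = beta2, eps = eps, t = 0L
  )
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / (1 - b1^opt$t)
    vhat <- opt$v[[i]] / (1 - b2^opt$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

#' Cosine-annealed learning rate
#'
#' Closed-form cosine schedule from `lr0` at epoch 1 down to `lr_min` at
#' epoch `total`.
#'
#' @param epoch Current epoch (1-based).
#' @param total Total number of epochs.
#' @param lr0 Initial learning rate.
#' @param lr_min Floor learning rate (default 0).
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, total, lr0, lr_min = 0) {
  if (total <= 1L) return(lr0)
  frac <- (epoch - 1) / (total - 1)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * frac))
}
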