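# Miniature trainable stand-ins for the full-scale architecture: a frozen
# convolutional image encoder with trainable adapter bottlenecks, compact
# student/teacher CNN-FPN detector backbones, a dense per-anchor detection
# head predicting objectness plus four edge-bin distributions, and a
# two-way-attention mask decoder. The mechanism under study (distilled
# feature prompting), not backbone scale, is the object of interest, so
# widths are chosen for CPU-minute training.

#' Frozen image encoder with adapters
#'
#' Four stride-2 convolution blocks map the image to a stride-16,
#' D-channel embedding. The backbone plays the role of a large pretrained
#' encoder: its weights are *frozen* (never updated). After each of the
#' last three blocks a residual adapter bottleneck
#' (1x1 down-projection, SiLU, 1x1 up-projection, zero-initialized) stays
#' trainable; with adapters disabled, or at their initialization, the
#' output equals the plain backbone output.
#'
#' @param spec A [model_spec()].
#' @return A list of class `image_encoder`.
#' @export
new_image_encoder <- function(spec = model_spec()) {
  w <- spec$encoder_width
  widths <- c(w, 2L * w, 3L * w, spec$embed_dim)
  blocks <- list(
    conv_layer(3L, 3L, 1L, widths[1L], trainable = FALSE),
    conv_layer(3L, 3L, widths[1L], widths[2L], trainable = FALSE),
    conv_layer(3L, 3L, widths[2L], widths[3L], trainable = FALSE),
    conv_layer(3L, 3L, widths[3L], widths[4L], trainable = FALSE)
  )
  adapters <- lapply(widths[2:4], function(ch) {
    ad <- list(down = conv_layer(1L, 1L, ch, spec$adapter_dim),
               up = conv_layer(1L, 1L, spec$adapter_dim, ch))
    ad$up$w$value[] <- 0   # identity at initialization
    ad$up$b$value[] <- 0
    ad
  })
  structure(list(blocks = blocks, adapters = adapters, spec = spec),
            class = "image_encoder")
}

#' Encode an image to a stride-16 embedding
#'
#' @param enc A [new_image_encoder()].
#' @param image An image matrix (values in `[0, 1]`), side divisible
#'   by 16.
#' @param adapters Apply the trainable adapter bottlenecks
#'   (default `TRUE`).
#' @return An autodiff node holding an (H/16, W/16, D) embedding.
#' @export
image_encoder <- function(enc, image, adapters = TRUE) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (any(dim(image)[1:2] %% 16L != 0L)) {
    abort("image resolution must be divisible by 16")
  }
  x <- as_ag(image)
  for (i in seq_along(enc$blocks)) {
    x <- conv_fwd(enc$blocks[[i]], x, stride = 2L, act = i < length(enc$blocks))
    if (adapters && i >= 2L) {
      ad <- enc$adapters[[i - 1L]]
      x <- ag_add(x, conv_fwd(ad$up, conv_fwd(ad$down, x, pad = 0L),
                              pad = 0L, act = FALSE))
    }
  }
  x
}

#' Detector backbone-neck producing a feature pyramid
#'
#' A compact CNN backbone (five stride-2 convolutions) with an FPN neck:
#' lateral 1x1 projections to a common width (twice the base width),
#' top-down bilinear upsampling with addition, and a 3x3 smoothing
#' convolution per level. Outputs P3/P4/P5 at strides 8/16/32. The
#' teacher uses `teacher_width`, giving it more than 6x the student's
#' parameters under the defaults.
#'
#' @param spec A [model_spec()].
#' @param role `"student"` or `"teacher"`.
#' @return A list of class `pyramid_net`.
#' @export
new_pyramid <- function(spec = model_spec(), role = c("student", "teacher")) {
  role <- match.arg(role)
  w <- if (role == "teacher") spec$teacher_width else spec$student_width
  f <- 2L * spec$student_width   # FPN width shared so prompt encoder widths fix
  if (role == "teacher") f <- 2L * spec$teacher_width
  structure(
    list(
      stem = list(
        conv_layer(3L, 3L, 1L, w),           # stride 2
        conv_layer(3L, 3L, w, 2L * w),       # stride 4
        conv_layer(3L, 3L, 2L * w, 2L * w),  # stride 8  -> C3
        conv_layer(3L, 3L, 2L * w, 3L * w),  # stride 16 -> C4
        conv_layer(3L, 3L, 3L * w, 4L * w)   # stride 32 -> C5
      ),
      lat = list(conv_layer(1L, 1L, 2L * w, f),
                 conv_layer(1L, 1L, 3L * w, f),
                 conv_layer(1L, 1L, 4L * w, f)),
      smooth = list(conv_layer(3L, 3L, f, f),
                    conv_layer(3L, 3L, f, f),
                    conv_layer(3L, 3L, f, f)),
      fpn_width = f, role = role, spec = spec
    ),
    class = "pyramid_net"
  )
}

#' Forward pass of a pyramid network
#'
#' @param net A [new_pyramid()].
#' @param image Image matrix; side divisible by 32.
#' @return List with autodiff nodes `P3`, `P4`, `P5` (strides 8/16/32).
#' @export
pyramid_forward <- function(net, image) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (any(dim(image)[1:2] %% 32L != 0L)) {
    abort("image resolution must be divisible by 32")
  }
  x <- as_ag(image)
  feats <- list()
  for (i in seq_along(net$stem)) {
    x <- conv_fwd(net$stem[[i]], x, stride = 2L)
    if (i >= 3L) feats[[i - 2L]] <- x     # C3, C4, C5
  }
  l3 <- conv_fwd(net$lat[[1L]], feats[[1L]], pad = 0L, act = FALSE)
  l4 <- conv_fwd(net$lat[[2L]], feats[[2L]], pad = 0L, act = FALSE)
  l5 <- conv_fwd(net$lat[[3L]], feats[[3L]], pad = 0L, act = FALSE)
  d4 <- dim(l4$value); d3 <- dim(l3$value)
  t4 <- ag_add(l4, ag_resize_bilinear(l5, d4[1L], d4[2L]))
  t3 <- ag_add(l3, ag_resize_bilinear(t4, d3[1L], d3[2L]))
  list(P3 = conv_fwd(net$smooth[[1L]], t3),
       P4 = conv_fwd(net$smooth[[2L]], t4),
       P5 = conv_fwd(net$smooth[[3L]], l5))
}

#' Dense detection head over a feature pyramid
#'
#' Per pyramid level, a 3x3 convolution plus a 1x1 projection predict, at
#' every cell, one objectness logit and `4 * bins` edge-distribution
#' logits (channel order: objectness, then top/bottom/left/right blocks of
#' `bins`). Anchors sit at cell centres with bin width equal to the level
#' stride.
#'
#' @param spec A [model_spec()].
#' @param fpn_width Channel width of the incoming pyramid.
#' @return A list of class `detection_head`.
#' @export
new_detection_head <- function(spec = model_spec(),
                               fpn_width = 2L * spec$student_width) {
  B <- spec$bins
  structure(
    list(
      conv = conv_layer(3L, 3L, fpn_width, fpn_width),
      proj = conv_layer(1L, 1L, fpn_width, 1L + 4L * B),
      spec = spec
    ),
    class = "detection_head"
  )
}

#' Run the detection head
#'
#' @param head A [new_detection_head()].
#' @param pyr Output of [pyramid_forward()].
#' @return A list of class `detection_output`: per-level output nodes
#'   (`levels`), an `anchors` tibble (one row per anchor, column-major per
#'   level, strides 8/16/32 stacked), and the flattened value matrices
#'   `obj` (vector) and `edges` (anchors x 4*bins).
#' @export
detection_forward <- function(head, pyr) {
  B <- head$spec$bins
  strides <- c(8L, 16L, 32L)
  levels <- list()
  anchors <- list()
  obj <- list()
  edges <- list()
  for (i in 1:3) {
    p <- pyr[[c("P3", "P4", "P5")[i]]]
    out <- conv_fwd(head$proj, conv_fwd(head$conv, p), pad = 0L, act = FALSE)
    d <- dim(out$value)
    levels[[i]] <- out
    anchors[[i]] <- anchor_grid(d[1L], d[2L], strides[i])
    flat <- matrix(out$value, d[1L] * d[2L], d[3L])
    obj[[i]] <- flat[, 1L]
    edges[[i]] <- flat[, -1L, drop = FALSE]
  }
  structure(
    list(levels = levels, anchors = dplyr::bind_rows(anchors),
         obj = unlist(obj), edges = do.call(rbind, edges),
         bins = B, n_per_level = vapply(levels, function(l)
           prod(dim(l$value)[1:2]), numeric(1))),
    class = "detection_output"
  )
}

# Vectorized decoding of all anchors' edge logits into boxes (expectation
# over bins at temperature 1). Returns a plain n x 4 matrix
# (xmin, ymin, xmax, ymax), one row per anchor; wrap with boxes() for the
# tibble form.
decode_all_anchors <- function(det) {
  B <- det$bins
  n <- nrow(det$anchors)
  dist <- matrix(0, n, 4L)
  idx <- seq_len(B) - 1
  for (e in 1:4) {
    z <- det$edges[, (e - 1L) * B + seq_len(B), drop = FALSE]
    z <- z - apply(z, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    dist[, e] <- (p %*% idx) * det$anchors$stride
  }
  cbind(xmin = det$anchors$cx - dist[, 3L],
        ymin = det$anchors$cy - dist[, 1L],
        xmax = det$anchors$cx + dist[, 4L],
        ymax = det$anchors$cy + dist[, 2L])
}

#' Two-way attention mask decoder
#'
#' The token set is the learned output mask token, concatenated with any
#' sparse prompt tokens and box-corner tokens. Each of L rounds applies
#' token self-attention, token-to-image cross-attention, and
#' image-to-token cross-attention (all residual). Mask logits are the
#' per-position dot product of an MLP-projected output token with the
#' embedding after two transposed-convolution upsamplings, followed by
#' bilinear resizing to the input resolution.
#'
#' @param spec A [model_spec()].
#' @return A list of class `mask_decoder`.
#' @export
new_mask_decoder <- function(spec = model_spec()) {
  D <- spec$embed_dim
  rounds <- lapply(seq_len(spec$decoder_rounds), function(i) {
    list(self = attn_layer(D, spec$heads),
         t2i = attn_layer(D, spec$heads),
         i2t = attn_layer(D, spec$heads))
  })
  structure(
    list(
      mask_token = ag_param(matrix(stats::rnorm(D, sd = 0.5), 1L, D)),
      rounds = rounds,
      up1 = convT_layer(4L, 4L, 32L, D),
      up2 = convT_layer(4L, 4L, 16L, 32L),
      token_mlp = linear_layer(D, 16L),
      spec = spec
    ),
    class = "mask_decoder"
  )
}

#' Decode a mask from a conditioned embedding and a prompt bundle
#'
#' @param dec A [new_mask_decoder()].
#' @param z_cond Conditioned image embedding (node or array,
#'   (h, w, D)).
#' @param tokens Optional list of extra token nodes/matrices
#'   (`n x D` each), e.g. sparse prompts and/or box tokens; may be empty.
#' @param out_size Output resolution (defaults to the spec's image size).
#' @return An autodiff node holding mask logits (out_size x out_size).
#' @export
mask_decoder <- function(dec, z_cond, tokens = list(),
                         out_size = dec$spec$image_size) {
  z_cond <- as_ag(z_cond)
  d <- dim(z_cond$value)
  D <- dec$spec$embed_dim
  if (d[3L] != D) abort("embedding and decoder dimension D must match")
  for (t in tokens) {
    if (ncol(ag_value(t)) != D) abort("token dimension must equal D")
  }
  tok <- ag_concat_rows(c(list(dec$mask_token), lapply(tokens, as_ag)))
  img <- ag_reshape(z_cond, c(d[1L] * d[2L], D))
  for (r in dec$rounds) {
    tok <- ag_add(tok, attn_fwd(r$self, tok, tok, tok))
    tok <- ag_add(tok, attn_fwd(r$t2i, tok, img, img))
    img <- ag_add(img, attn_fwd(r$i2t, img, tok, tok))
  }
  emb <- ag_reshape(img, d)
  up <- convT_fwd(dec$up2, convT_fwd(dec$up1, emb, pad = 1L), pad = 1L)  # 4x upscale
  t0 <- linear_fwd(dec$token_mlp, ag_rows(tok, 1L))        # 1 x 16
  du <- dim(up$value)
  flat <- ag_reshape(up, c(du[1L] * du[2L], du[3L]))
  logits <- ag_matmul(flat, ag_transpose(t0))              # (h*w) x 1
  logits <- ag_reshape(logits, c(du[1L], du[2L], 1L))
  out <- ag_resize_bilinear(logits, out_size, out_size)
  ag_reshape(out, c(out_size, out_size))
}
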