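# Dual-stream prompt encoder: multi-scale pyramid fusion -> dense feature
# prompt (pixel-wise, injected residually into the image embedding through
# a zero-initialized learnable gate) + sparse feature prompts (K global
# tokens that join the decoder's attention), plus sinusoidal box-corner
# tokens for the geometric-prompt baseline arm.

#' Miniature model specification
#'
#' Widths and depths of every trainable component, sized so that full
#' two-phase training runs in CPU minutes. The teacher pyramid is strictly
#' higher-capacity than the student (width factor >= 2.5, i.e. > 6x the
#' parameters), mirroring the large teacher/student capacity gap the
#' distillation relies on.
#'
#' @param image_size Input resolution (divisible by 32; default 64).
#' @param embed_dim D, the image-embedding / prompt-token dimension
#'   (default 32).
#' @param fused_channels C, channels of the fused stride-8 feature map
#'   (default 32).
#' @param n_sparse K, number of sparse prompt tokens (default 4).
#' @param bins B, spatial bins per box edge (default 8; bin width equals
#'   the anchor stride).
#' @param student_width,teacher_width Base channel width of the student /
#'   teacher detector backbones (defaults 8 / 20). Pyramid outputs have
#'   twice the base width at every level.
#' @param encoder_width Base width of the frozen image-encoder stand-in
#'   (default 8).
#' @param adapter_dim Bottleneck width of the encoder adapters (default 4).
#' @param decoder_rounds L, two-way attention rounds in the mask decoder
#'   (default 2).
#' @param heads Attention heads (default 2).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(image_size = 64L, embed_dim = 32L,
                       fused_channels = 32L, n_sparse = 4L, bins = 8L,
                       student_width = 8L, teacher_width = 20L,
                       encoder_width = 8L, adapter_dim = 4L,
                       decoder_rounds = 2L, heads = 2L) {
  if (image_size %% 32L != 0L) abort("`image_size` must be divisible by 32")
  if (bins < 2L) abort("`bins` must be >= 2")
  if (n_sparse < 1L) abort("`n_sparse` must be >= 1")
  if (teacher_width <= student_width) {
    abort("teacher capacity must exceed student capacity")
  }
  structure(
    list(image_size = as.integer(image_size), embed_dim = as.integer(embed_dim),
         fused_channels = as.integer(fused_channels),
         n_sparse = as.integer(n_sparse), bins = as.integer(bins),
         student_width = as.integer(student_width),
         teacher_width = as.integer(teacher_width),
         encoder_width = as.integer(encoder_width),
         adapter_dim = as.integer(adapter_dim),
         decoder_rounds = as.integer(decoder_rounds),
         heads = as.integer(heads)),
    class = "model_spec"
  )
}

#' Construct a prompt encoder
#'
#' Holds the mixing block for pyramid fusion, the strided dense-prompt
#' head, the GAP + MLP sparse-prompt head, the learnable injection gate
#' `alpha` (initialized to exactly 0, so at initialization the conditioned
#' embedding equals the raw embedding), and the learned corner-type
#' embeddings for box-prompt tokens.
#'
#' @param spec A [model_spec()].
#' @return A list of class `prompt_encoder`.
#' @export
new_prompt_encoder <- function(spec = model_spec()) {
  cin <- 3L * (2L * spec$student_width)  # concat of P3 + up(P4) + up(P5)
  C <- spec$fused_channels
  D <- spec$embed_dim
  K <- spec$n_sparse
  structure(
    list(
      mix1 = conv_layer(1L, 1L, cin, C),
      mix3 = conv_layer(3L, 3L, C, C),
      dense_head = conv_layer(3L, 3L, C, D),
      mlp1 = linear_layer(C, 2L * K * D),
      mlp2 = linear_layer(2L * K * D, K * D),
      corner_embed = ag_param(he_init(c(2L, D), D)),
      alpha = ag_param(0),
      spec = spec
    ),
    class = "prompt_encoder"
  )
}

#' Fuse a multi-scale feature pyramid to stride 8
#'
#' Bilinearly upsamples P4 and P5 to P3's resolution (half-pixel-centre
#' sampling, no corner alignment), concatenates the three levels along
#' channels, and applies the mixing block: a 1x1 convolution for channel
#' reduction followed by a 3x3 convolution for spatial smoothing (both
#' SiLU-activated). The output keeps P3's spatial size (stride 8) with
#' `fused_channels` channels.
#'
#' @param pe A [new_prompt_encoder()].
#' @param pyr A feature pyramid: list with elements `P3`, `P4`, `P5`
#'   (autodiff nodes or plain (H, W, C) arrays).
#' @return An autodiff node; use `$value` for the array.
#' @export
fuse_pyramid <- function(pe, pyr) {
  p3 <- as_ag(pyr$P3); p4 <- as_ag(pyr$P4); p5 <- as_ag(pyr$P5)
  d3 <- dim(p3$value); d4 <- dim(p4$value); d5 <- dim(p5$value)
  if (!all(d3[1:2] == 2L * d4[1:2]) || !all(d4[1:2] == 2L * d5[1:2])) {
    abort("pyramid spatial dims must halve from P3 to P4 to P5")
  }
  up4 <- ag_resize_bilinear(p4, d3[1L], d3[2L])
  up5 <- ag_resize_bilinear(p5, d3[1L], d3[2L])
  x <- ag_concat_channels(list(p3, up4, up5))
  conv_fwd(pe$mix3, conv_fwd(pe$mix1, x, pad = 0L))
}

#' Dense feature prompt from the fused map
#'
#' A stride-2 3x3 convolutional head that halves the fused map's
#' resolution (stride 8 to stride 16, matching the image embedding) and
#' maps channels to the embedding dimension D. Odd input sizes are
#' handled by the convolution's symmetric zero padding.
#'
#' @param pe A [new_prompt_encoder()].
#' @param fused Output of [fuse_pyramid()].
#' @return An autodiff node holding the stride-16, D-channel prompt map.
#' @export
dense_prompt <- function(pe, fused) {
  conv_fwd(pe$dense_head, as_ag(fused), stride = 2L, act = FALSE)
}

#' Inject the dense prompt into the image embedding
#'
#' The residual conditioning `Z_cond = Z_img + alpha * P_dense` with a
#' single learnable scalar gate `alpha`. At `alpha = 0` (its
#' initialization) the conditioned embedding is identical to the input,
#' so the prompt path is strictly additive.
#'
#' @param z_img Image embedding (node or array, stride 16, D channels).
#' @param p_dense Dense prompt of the same shape.
#' @param alpha Scalar gate (an `ag_param`, or a plain number).
#' @return An autodiff node of the same shape as `z_img`.
#' @export
inject_dense <- function(z_img, p_dense, alpha) {
  z_img <- as_ag(z_img); p_dense <- as_ag(p_dense); alpha <- as_ag(alpha)
  if (!identical(dim(z_img$value), dim(p_dense$value))) {
    abort("`z_img` and `p_dense` must have identical shapes")
  }
  ag_add(z_img, ag_scale(p_dense, alpha))
}

#' Sparse feature prompts from the fused map
#'
#' Global average pooling squeezes the fused map to a channel vector,
#' which a two-layer perceptron (C -> 2KD, SiLU, -> KD) projects and
#' logically partitions into K independent tokens of dimension D.
#'
#' @param pe A [new_prompt_encoder()].
#' @param fused Output of [fuse_pyramid()].
#' @return An autodiff node holding a K x D token matrix.
#' @export
sparse_prompt <- function(pe, fused) {
  v <- ag_gap(as_ag(fused))
  h <- linear_fwd(pe$mlp1, ag_reshape(v, c(1L, length(v$value))), act = TRUE)
  out <- linear_fwd(pe$mlp2, h)
  ag_reshape(out, c(pe$spec$n_sparse, pe$spec$embed_dim))
}

# Fixed sinusoidal positional embedding of a 2D point (normalized coords).
sincos_embed <- function(x, y, d) {
  nf <- d %/% 4L
  freqs <- 2 * pi * 2^(seq_len(nf) - 1L)
  out <- c(sin(freqs * x), cos(freqs * x), sin(freqs * y), cos(freqs * y))
  c(out, numeric(d - length(out)))
}

#' Box-corner prompt tokens (geometric baseline)
#'
#' Encodes a box as two tokens - one per corner (top-left, then
#' bottom-right) - each the fixed sinusoidal positional embedding of the
#' corner's normalized coordinates plus a learned corner-type embedding.
#' Deterministic given the parameters. Boxes extending beyond the image
#' are clamped with a warning.
#'
#' @param pe A [new_prompt_encoder()].
#' @param box A one-row box tibble.
#' @param image_size Image side length used for normalization (defaults
#'   to the spec's).
#' @return An autodiff node holding a 2 x D token matrix.
#' @export
box_prompt_tokens <- function(pe, box, image_size = pe$spec$image_size) {
  box <- validate_boxes(box)
  stopifnot(nrow(box) == 1L)
  if (box$xmin < 0 || box$ymin < 0 ||
      box$xmax > image_size || box$ymax > image_size) {
    rlang::warn("box extends beyond the image; clamping to bounds")
    box$xmin <- max(box$xmin, 0); box$ymin <- max(box$ymin, 0)
    box$xmax <- min(box$xmax, image_size); box$ymax <- min(box$ymax, image_size)
  }
  d <- pe$spec$embed_dim
  pos <- rbind(sincos_embed(box$xmin / image_size, box$ymin / image_size, d),
               sincos_embed(box$xmax / image_size, box$ymax / image_size, d))
  ag_add(ag_input(pos), pe$corner_embed)
}
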