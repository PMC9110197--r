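# Network building blocks.
#
# Each block is an environment holding its layers plus two testing hooks:
# `force_gate` (set to 0 or 1 to replace the learned gate by a constant,
# exposing the closed-form residual limits) and `last_gate` (the gate values
# recorded during the most recent forward pass). Blocks consume and produce
# ag_tensors; `as_feature_map()` lifts plain arrays.

new_block <- function(.kind, ...) {
  b <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = b)
  b$kind <- .kind
  b$force_gate <- NULL
  b$last_gate <- NULL
  class(b) <- c(paste0("apu_", .kind), "apu_block")
  b
}

#' Lift an image or feature array to a network tensor
#'
#' Accepts a matrix (H x W), a 3-d array (H x W x C) or a 4-d array
#' (H x W x C x N) and returns a constant tensor of shape (H, W, C, N).
#'
#' @param x numeric matrix or array.
#' @return an internal tensor object; its `$value` is the 4-d array.
#' @export
as_feature_map <- function(x) {
  if (is_tensor(x)) return(x)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  ag_const(x)
}

const_like <- function(v, value_dim) ag_const(array(v, value_dim))

# ---- double convolution block --------------------------------------------

#' Create a double convolution block
#'
#' Two rounds of (3x3 convolution with same padding, batch normalization,
#' ReLU), the elementary unit of every encoder and decoder stage.
#'
#' @param in_ch,out_ch input and output channel counts.
#' @return a block object; run it with [block_forward()].
#' @export
new_conv_block <- function(in_ch, out_ch) {
  b <- new_block("conv_block",
                 c1 = nn_conv2d(in_ch, out_ch), n1 = nn_batchnorm(out_ch),
                 c2 = nn_conv2d(out_ch, out_ch), n2 = nn_batchnorm(out_ch),
                 in_ch = in_ch, out_ch = out_ch)
  b$layers <- list(b$c1, b$n1, b$c2, b$n2)
  b
}

fwd_conv_block <- function(b, x, training = FALSE) {
  h <- op_relu(op_batchnorm(op_conv2d(x, b$c1$w, b$c1$b),
                            b$n1$gamma, b$n1$beta, b$n1, training))
  op_relu(op_batchnorm(op_conv2d(h, b$c2$w, b$c2$b),
                       b$n2$gamma, b$n2$beta, b$n2, training))
}

# ---- two-modal feature-extraction gate -----------------------------------

#' Create a two-modal feature-extraction block
#'
#' Fuses same-scale features from the fused-image encoder and the PET
#' encoder: the two maps are concatenated, a learned sigmoid gate with one
#' weight per channel and pixel is computed from the concatenation, and the
#' concatenation is multiplied by the gate. The default gate path is
#' 1x1 convolution + ReLU, then 3x3 convolution, then sigmoid; set
#' `text_variant = TRUE` for the all-1x1 alternative.
#'
#' @param ch channels of each input map (the output has `2 * ch`).
#' @param text_variant logical; use the two 1x1-convolution gate path.
#' @return a block object.
#' @export
new_two_modal_block <- function(ch, text_variant = FALSE) {
  cc <- 2L * ch
  k2 <- if (text_variant) 1 else 3
  b <- new_block("two_modal",
                 g1 = nn_conv2d(cc, cc, 1), g2 = nn_conv2d(cc, cc, k2),
                 ch = ch, text_variant = text_variant)
  b$layers <- list(b$g1, b$g2)
  b
}

fwd_two_modal <- function(b, x1, x2, training = FALSE) {
  cc <- op_concat(list(x1, x2))
  if (!is.null(b$force_gate)) {
    g <- const_like(b$force_gate, dim(cc$value))
  } else {
    h <- op_relu(op_conv2d(cc, b$g1$w, b$g1$b))
    g <- op_sigmoid(op_conv2d(h, b$g2$w, b$g2$b))
  }
  b$last_gate <- g$value
  op_mul(cc, g)
}

# ---- spatial attention ----------------------------------------------------

#' Create a spatial attention block
#'
#' Channel-wise mean and max maps of the input are stacked, convolved (3x3)
#' to one channel, and squashed by a sigmoid into a spatial gate `s` in
#' \[0,1\]; the block returns `x + x * s` (residual form).
#'
#' @return a block object.
#' @export
new_spatial_attention <- function() {
  b <- new_block("spatial_attention", conv = nn_conv2d(2, 1, 3))
  b$layers <- list(b$conv)
  b
}

fwd_spatial_attention <- function(b, x, training = FALSE) {
  d <- dims_hwcn(x$value)
  if (!is.null(b$force_gate)) {
    s <- const_like(b$force_gate, c(d$H, d$W, 1, d$N))
  } else {
    mm <- op_channel_meanmax(x)
    s <- op_sigmoid(op_conv2d(mm, b$conv$w, b$conv$b))
  }
  b$last_gate <- s$value
  op_add(x, op_scale_spatial(x, s))
}

# ---- channel attention ----------------------------------------------------

#' Create a channel attention block
#'
#' Global average- and max-pooled channel vectors pass through a shared
#' bias-free two-layer perceptron (hidden width `floor(ch / 3)`, ReLU); the
#' two outputs are summed and a sigmoid yields per-channel weights `alpha`.
#' The block returns `x * alpha + x`.
#'
#' @param ch channel count of the input; must be at least 3.
#' @return a block object.
#' @export
new_channel_attention <- function(ch) {
  if (ch < 3) stop("channel attention needs at least 3 channels (hidden ",
                   "width floor(ch/3) would be 0)")
  hidden <- floor(ch / 3)
  b <- new_block("channel_attention",
                 fc1 = nn_linear(ch, hidden), fc2 = nn_linear(hidden, ch),
                 ch = ch, hidden = hidden)
  b$layers <- list(b$fc1, b$fc2)
  b
}

fwd_channel_attention <- function(b, x, training = FALSE) {
  d <- dims_hwcn(x$value)
  if (!is.null(b$force_gate)) {
    alpha <- ag_const(matrix(b$force_gate, d$N, d$C))
  } else {
    mlp <- function(v) op_linear(op_relu(op_linear(v, b$fc1$w)), b$fc2$w)
    a <- mlp(op_global_avgpool(x))
    m <- mlp(op_global_maxpool(x))
    alpha <- op_sigmoid(op_add(a, m))
  }
  b$last_gate <- alpha$value
  op_add(op_scale_channel(x, alpha), x)
}

# ---- hybrid attention -----------------------------------------------------

#' Create a hybrid attention block
#'
#' Concatenates the fused-branch and CT-branch feature maps and applies
#' channel attention followed by spatial attention (order configurable).
#'
#' @param ch_hybrid,ch_ct channel counts of the two inputs.
#' @param order character vector giving the attention order.
#' @return a block object.
#' @export
new_hybrid_attention <- function(ch_hybrid, ch_ct,
                                 order = c("channel", "spatial")) {
  ch <- ch_hybrid + ch_ct
  b <- new_block("hybrid_attention",
                 ca = new_channel_attention(ch), sa = new_spatial_attention(),
                 ch = ch, order = order)
  b$layers <- list(b$ca, b$sa)
  b
}

fwd_hybrid_attention <- function(b, f_hybrid, f_ct, training = FALSE) {
  x <- op_concat(list(f_hybrid, f_ct))
  for (step in b$order) {
    x <- if (step == "channel") fwd_channel_attention(b$ca, x, training)
         else fwd_spatial_attention(b$sa, x, training)
  }
  x
}

# ---- multiscale feature aggregation --------------------------------------

#' Create a multiscale feature-aggregation block
#'
#' For each of the four decoder scales the two decoders' maps are
#' concatenated, resampled bilinearly to `out_size` pixels and compressed by
#' a 1x1 convolution to `per_scale_ch` channels; the four results are
#' concatenated into `F`. A channel weight `alpha = sigmoid(MLP(avgpool(F)))`
#' and a map weight `beta = sigmoid(Conv1x1(ReLU(Conv3x3(F * alpha))))` then
#' combine residually as `F * alpha * beta + F * alpha + F`.
#'
#' @param in_ch integer vector of length 4: concatenated channel count at
#'   each scale (coarsest first).
#' @param out_size output side length in pixels.
#' @param per_scale_ch channels kept per scale after compression.
#' @return a block object.
#' @export
new_mfa_block <- function(in_ch, out_size = 50, per_scale_ch = 16) {
  stopifnot(length(in_ch) == 4)
  ftot <- 4L * per_scale_ch
  hidden <- floor(ftot / 3)
  b <- new_block("mfa",
                 compress = lapply(in_ch, function(ci)
                   nn_conv2d(ci, per_scale_ch, 1)),
                 fc1 = nn_linear(ftot, hidden), fc2 = nn_linear(hidden, ftot),
                 bc3 = nn_conv2d(ftot, ftot, 3), bc1 = nn_conv2d(ftot, ftot, 1),
                 out_size = out_size, per_scale_ch = per_scale_ch,
                 ftot = ftot)
  b$force_alpha <- NULL
  b$force_beta <- NULL
  b$layers <- list(b$compress, b$fc1, b$fc2, b$bc3, b$bc1)
  b
}

fwd_mfa <- function(b, pairs, training = FALSE) {
  if (length(pairs) != 4) stop("MFA block expects 4 decoder scales")
  scaled <- lapply(seq_along(pairs), function(i) {
    cc <- op_concat(list(pairs[[i]][[1]], pairs[[i]][[2]]))
    rs <- op_bilinear(cc, b$out_size, b$out_size)
    op_conv2d(rs, b$compress[[i]]$w, b$compress[[i]]$b)
  })
  f <- op_concat(scaled)
  d <- dims_hwcn(f$value)
  if (!is.null(b$force_alpha)) {
    alpha <- ag_const(matrix(b$force_alpha, d$N, d$C))
  } else {
    alpha <- op_sigmoid(op_linear(
      op_relu(op_linear(op_global_avgpool(f), b$fc1$w)), b$fc2$w))
  }
  fa <- op_scale_channel(f, alpha)
  if (!is.null(b$force_beta)) {
    beta <- const_like(b$force_beta, dim(f$value))
  } else {
    h <- op_relu(op_conv2d(fa, b$bc3$w, b$bc3$b))
    beta <- op_sigmoid(op_conv2d(h, b$bc1$w, b$bc1$b))
  }
  b$last_gate <- list(alpha = alpha$value, beta = beta$value)
  op_add(op_add(op_mul(fa, beta), fa), f)
}

#' Run a block forward
#'
#' Dispatches on the block kind; inputs may be plain arrays or tensors.
#' Returns the output tensor (`$value` holds the array).
#'
#' @param block a block created by one of the `new_*` constructors.
#' @param ... block inputs (one feature map, two for the fusion/attention
#'   blocks, or a list of four scale pairs for the MFA block).
#' @param training logical; batch-norm statistics update mode.
#' @return an ag_tensor.
#' @export
block_forward <- function(block, ..., training = FALSE) {
  ins <- lapply(list(...), function(x)
    if (is.list(x) && !is_tensor(x)) lapply(x, function(p)
      if (is.list(p) && !is_tensor(p)) lapply(p, as_feature_map)
      else as_feature_map(p))
    else as_feature_map(x))
  switch(block$kind,
    conv_block = fwd_conv_block(block, ins[[1]], training),
    two_modal = fwd_two_modal(block, ins[[1]], ins[[2]], training),
    spatial_attention = fwd_spatial_attention(block, ins[[1]], training),
    channel_attention = fwd_channel_attention(block, ins[[1]], training),
    hybrid_attention = fwd_hybrid_attention(block, ins[[1]], ins[[2]],
                                            training),
    mfa = fwd_mfa(block, ins[[1]], training),
    stop("unknown block kind ", block$kind)
  )
}
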