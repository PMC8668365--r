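#' @importFrom stats runif
NULL

# He-uniform initialisation: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

new_conv_param <- function(kh, kw, cin, cout, name) {
  ag_param(kaiming_uniform(c(kh, kw, cin, cout), kh * kw * cin), name = name)
}

new_affine_params <- function(c, name) {
  list(gamma = ag_param(rep(1, c), name = paste0(name, ".gamma")),
       beta = ag_param(rep(0, c), name = paste0(name, ".beta")))
}

#' Parameters of one CIIP block
#'
#' Creates the learnable parameters of a channel information interaction
#' perception (CIIP) block: the 1x1 -> 3x3 -> 1x1 bottleneck of the
#' convolutional short connection (each convolution followed by layer
#' normalization and ReLU), and — only when the block receives the attention
#' vector of a predecessor (`prev_channels` given) — the channel-matching
#' linear map (`fc_match`, followed by LayerNorm and ReLU) plus the 1x1
#' attention convolution (`att_conv`, followed by LayerNorm and Sigmoid)
#' that fuse the incoming attention weights with the pooled features.
#'
#' A first-branch block (no `prev_channels`) carries no learned attention
#' parameters at all: its gate is the plain sigmoid of the pooled features.
#'
#' @param channels number of channels `C` of the feature map entering the block.
#' @param prev_channels channel count of the predecessor's attention vector,
#'   or `NULL` for a first-branch block.
#' @param reduction bottleneck reduction ratio; `channels` must be divisible
#'   by it.  Default 4, matching the backbone's 1x1/3x3/1x1 channel pattern
#'   (e.g. 256 -> 64 -> 64 -> 256).
#' @param att_norm apply LayerNorm inside the attention convolution
#'   composite (the standard configuration).  Disabling it turns `att_conv`
#'   into a plain linear gate, which is occasionally useful for analysing
#'   the block in isolation.
#' @return an object of class `ciip_params`.  Parameter values live in
#'   `$params` as named arrays-with-state and are drawn from the current RNG
#'   stream (He-uniform for weights), so results are reproducible under
#'   [set.seed()].
#' @export
ciip_params <- function(channels, prev_channels = NULL, reduction = 4,
                        att_norm = TRUE) {
  stopifnot(channels >= 1)
  if (channels %% reduction != 0) {
    stop(sprintf("channels (%d) must be divisible by the reduction ratio (%d)",
                 channels, reduction), call. = FALSE)
  }
  cr <- channels %/% reduction
  p <- list(
    w_reduce = new_conv_param(1, 1, channels, cr, "ciip.w_reduce"),
    ln1 = new_affine_params(cr, "ciip.ln1"),
    w_mid = new_conv_param(3, 3, cr, cr, "ciip.w_mid"),
    ln2 = new_affine_params(cr, "ciip.ln2"),
    w_restore = new_conv_param(1, 1, cr, channels, "ciip.w_restore"),
    ln3 = new_affine_params(channels, "ciip.ln3")
  )
  if (!is.null(prev_channels)) {
    p$fc_w <- ag_param(kaiming_uniform(c(channels, prev_channels), prev_channels),
                       name = "ciip.fc_match")
    p$fc_ln <- new_affine_params(channels, "ciip.fc_ln")
    p$att_w <- ag_param(kaiming_uniform(c(channels, channels), channels),
                        name = "ciip.att_conv")
    if (att_norm) p$att_ln <- new_affine_params(channels, "ciip.att_ln")
  }
  structure(
    list(channels = channels, prev_channels = prev_channels,
         reduction = reduction, att_norm = att_norm, params = p),
    class = "ciip_params"
  )
}

# Flat list of the block's parameter nodes (for optimizers / counting).
ciip_param_nodes <- function(pr) {
  p <- pr$params
  out <- list(p$w_reduce, p$ln1$gamma, p$ln1$beta, p$w_mid, p$ln2$gamma,
              p$ln2$beta, p$w_restore, p$ln3$gamma, p$ln3$beta)
  if (!is.null(p$fc_w)) {
    out <- c(out, list(p$fc_w, p$fc_ln$gamma, p$fc_ln$beta, p$att_w))
    if (!is.null(p$att_ln)) out <- c(out, list(p$att_ln$gamma, p$att_ln$beta))
  }
  out
}

#' Serialize CIIP block parameters to plain arrays
#'
#' Returns a named list of numeric arrays.  First-branch blocks store no
#' `fc_match`/`att_conv` entries, since they have none.
#'
#' @param params a [ciip_params()] object.
#' @export
ciip_params_values <- function(params) {
  nodes <- ciip_param_nodes(params)
  vals <- lapply(nodes, function(n) n$value)
  names(vals) <- vapply(nodes, function(n) n$name, character(1))
  vals
}

# ---- internal (tape-level) forward pieces --------------------------------

ciip_bottleneck_fwd <- function(tape, x, pr) {
  p <- pr$params
  h <- op_conv(tape, x, p$w_reduce)
  h <- op_relu(tape, op_layernorm_fm(tape, h, p$ln1$gamma, p$ln1$beta))
  h <- op_conv(tape, h, p$w_mid, stride = 1L, pad = 1L)
  h <- op_relu(tape, op_layernorm_fm(tape, h, p$ln2$gamma, p$ln2$beta))
  h <- op_conv(tape, h, p$w_restore)
  h <- op_relu(tape, op_layernorm_fm(tape, h, p$ln3$gamma, p$ln3$beta))
  op_add(tape, x, h)
}

ciip_attention_first_fwd <- function(tape, x) {
  g <- op_gap(tape, x)
  s <- op_sigmoid(tape, g)
  list(output = op_scale_channels(tape, x, s), att = op_mul(tape, s, g))
}

ciip_attention_followup_fwd <- function(tape, x, att_prev, pr) {
  p <- pr$params
  if (is.null(p$fc_w)) {
    stop("this CIIP block was built without fc_match/att_conv parameters; ",
         "it cannot consume an incoming attention vector", call. = FALSE)
  }
  if (nrow(att_prev$value) != ncol(p$fc_w$value)) {
    stop(sprintf(
      "incoming attention has length %d but fc_match expects %d",
      nrow(att_prev$value), ncol(p$fc_w$value)), call. = FALSE)
  }
  a <- op_linear(tape, att_prev, p$fc_w)
  a <- op_relu(tape, op_layernorm_vec(tape, a, p$fc_ln$gamma, p$fc_ln$beta))
  g <- op_gap(tape, x)
  z <- op_linear(tape, op_add(tape, a, g), p$att_w)
  if (!is.null(p$att_ln)) {
    z <- op_layernorm_vec(tape, z, p$att_ln$gamma, p$att_ln$beta)
  }
  m <- op_sigmoid(tape, z)
  list(output = op_scale_channels(tape, x, m), att = op_mul(tape, m, g))
}

ciip_fwd <- function(tape, x, att_prev, pr) {
  h <- ciip_bottleneck_fwd(tape, x, pr)
  if (is.null(att_prev)) {
    ciip_attention_first_fwd(tape, h)
  } else {
    ciip_attention_followup_fwd(tape, h, att_prev, pr)
  }
}

# ---- user-facing array API ----------------------------------------------

as_batch <- function(x) {
  if (length(dim(x)) == 3) {
    list(x = array(x, c(dim(x), 1L)), single = TRUE)
  } else if (length(dim(x)) == 4) {
    list(x = x, single = FALSE)
  } else {
    stop("feature map must be an [H, W, C] or [H, W, C, N] array", call. = FALSE)
  }
}

as_att_batch <- function(a) {
  if (is.matrix(a)) a else matrix(a, length(a), 1L)
}

unbatch <- function(v, single) {
  if (!single) return(v)
  d <- dim(v)
  if (length(d) == 4) array(v, d[1:3]) else as.vector(v)
}

check_ciip_input <- function(x, params) {
  d <- dim(x)
  if (d[3] != params$channels) {
    stop(sprintf("feature map has %d channels but the block expects %d",
                 d[3], params$channels), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("feature map contains non-finite values", call. = FALSE)
}

#' Convolutional short connection of a CIIP block
#'
#' The residual bottleneck at the entrance of every CIIP block: a 1x1
#' channel-reducing convolution, a 3x3 convolution, and a 1x1
#' channel-restoring convolution (each followed by LayerNorm and ReLU),
#' added elementwise to the input.  It deepens the network while preserving
#' the feature map's shape and information.
#'
#' @param x a feature map, `[H, W, C]` or `[H, W, C, N]` array.
#' @param params a [ciip_params()] object with matching `channels`.
#' @return a feature map of identical shape.
#' @export
bottleneck_short_connection <- function(x, params) {
  b <- as_batch(x)
  check_ciip_input(b$x, params)
  tape <- ag_tape()
  out <- ciip_bottleneck_fwd(tape, ag_const(b$x), params)
  unbatch(out$value, b$single)
}

#' First-branch CIIP attention (no incoming attention)
#'
#' Implements the gate of the first CIIP block: with `g` the channelwise
#' spatial mean (GAP) of `x` and `s = sigmoid(g)`, the output feature map is
#' `s[c] * x[c, , ]` and the emitted attention weight is `Att[c] = s[c] * g[c]`.
#'
#' @param x a feature map (normally the output of
#'   [bottleneck_short_connection()]), `[H, W, C]` or `[H, W, C, N]`.
#' @return `list(output, att)`: the gated feature map (same shape as `x`)
#'   and the attention weight vector (length `C`, or a `C x N` matrix for a
#'   batch) to pass to the next CIIP block.
#' @export
attention_first <- function(x) {
  b <- as_batch(x)
  if (!all(is.finite(b$x))) stop("feature map contains non-finite values", call. = FALSE)
  tape <- ag_tape()
  res <- ciip_attention_first_fwd(tape, ag_const(b$x))
  list(output = unbatch(res$output$value, b$single),
       att = unbatch(res$att$value, b$single))
}

#' Follow-up CIIP attention (consuming a predecessor's attention)
#'
#' Implements the gate of the second and third CIIP blocks.  The incoming
#' attention vector is passed through the channel-matching linear map
#' (LayerNorm + ReLU), added elementwise to the pooled features `g`, pushed
#' through the 1x1 attention convolution composite and a sigmoid to give a
#' single gate `m`; the block returns `m[c] * x[c, , ]` and `Att[c] = m[c] * g[c]`.
#'
#' @inheritParams bottleneck_short_connection
#' @param att_prev attention weights emitted by the previous CIIP block:
#'   a vector of length `C_prev` or a `C_prev x N` matrix.
#' @return `list(output, att)` as in [attention_first()].
#' @export
attention_followup <- function(x, att_prev, params) {
  b <- as_batch(x)
  check_ciip_input(b$x, params)
  a <- as_att_batch(att_prev)
  if (ncol(a) != dim(b$x)[4]) a <- matrix(a, nrow(a), dim(b$x)[4])
  tape <- ag_tape()
  res <- ciip_attention_followup_fwd(tape, ag_const(b$x), ag_const(a), params)
  list(output = unbatch(res$output$value, b$single),
       att = unbatch(res$att$value, b$single))
}

#' Full CIIP block forward pass
#'
#' Applies the convolutional short connection and then dispatches on the
#' presence of the incoming attention vector: absent (first block in the
#' chain) uses the parameter-free sigmoid gate of [attention_first()];
#' present uses [attention_followup()].  The returned attention vector is
#' what the next CIIP block consumes, so chained calls realise the
#' feed-forward flow of attention information between modules.
#'
#' @inheritParams attention_followup
#' @param att_prev incoming attention weights, or `NULL` when no predecessor
#'   exists.
#' @return `list(output, att)`.
#' @export
ciip_forward <- function(x, att_prev = NULL, params) {
  h <- bottleneck_short_connection(x, params)
  if (is.null(att_prev)) {
    attention_first(h)
  } else {
    attention_followup(h, att_prev, params)
  }
}
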