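# Differentiable layer operations used to assemble CIIP blocks and the
# IIP-Net backbone.  Feature maps are arrays [H, W, C, N]; pooled channel
# descriptors are matrices [C, N].

# ---- broadcasting helpers ------------------------------------------------

# per-(channel, sample) spatial sums of an [H, W, C, N] array -> [C, N]
# (.colSums avoids the reshape copy of matrix())
spatial_sum_cn <- function(x) {
  d <- dim(x)
  matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

# broadcast a length-C vector over [H, W, C, N] (R recycles over N)
bcast_c <- function(v, d) rep(v, each = d[1] * d[2])

# broadcast a [C, N] matrix over [H, W, C, N]
bcast_cn <- function(s, d) rep(as.vector(s), each = d[1] * d[2])

# ---- convolution / pooling ----------------------------------------------

op_conv <- function(tape, x, w, stride = 1L, pad = 0L) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  if (xd[3] != wd[3]) {
    stop(sprintf("channel mismatch: input has %d channels, weights expect %d",
                 xd[3], wd[3]), call. = FALSE)
  }
  val <- cpp_conv2d_forward(x$value, xd, w$value, wd, stride, pad)
  xv <- x$value
  wv <- w$value
  ag_node(val, parents = list(x, w), tape = tape, vjp = function(g) {
    dim(g) <- dim(val)
    list(cpp_conv2d_backward_input(g, xd, wv, wd, stride, pad),
         cpp_conv2d_backward_weight(xv, xd, g, wd, stride, pad))
  })
}

op_maxpool <- function(tape, x, k = 3L, stride = 2L, pad = 1L) {
  xd <- dim(x$value)
  fw <- cpp_maxpool_forward(x$value, xd, k, stride, pad)
  idx <- fw$idx
  ag_node(fw$value, parents = list(x), tape = tape, vjp = function(g) {
    dim(g) <- dim(fw$value)
    list(cpp_maxpool_backward(g, idx, xd))
  })
}

# ---- normalization -------------------------------------------------------

# Batch normalization over (H, W, N) per channel, with running statistics
# for evaluation mode kept in `state` (an environment).  Forward and
# backward are fused C++ passes.
op_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  if (training) {
    st <- cpp_channel_stats(x$value, d)
    mu <- st$mean
    va <- st$var
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- va
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * va
    }
  } else {
    mu <- if (is.null(state$mean)) numeric(d[3]) else state$mean
    va <- if (is.null(state$var)) rep(1, d[3]) else state$var
  }
  invstd <- 1 / sqrt(va + eps)
  val <- cpp_bn_forward(x$value, d, gamma$value, beta$value, mu, invstd)
  xv <- x$value
  gv <- gamma$value
  ag_node(val, parents = list(x, gamma, beta), tape = tape, vjp = function(g) {
    bw <- cpp_bn_backward(g, xv, d, gv, mu, invstd, training)
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

# Layer normalization of a feature map: per sample over all of (H, W, C),
# learnable per-channel affine.  Fused C++ passes.
op_layernorm_fm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  fw <- cpp_ln_forward(x$value, d, gamma$value, beta$value, eps)
  xv <- x$value
  gv <- gamma$value
  ag_node(fw$y, parents = list(x, gamma, beta), tape = tape, vjp = function(g) {
    bw <- cpp_ln_backward(g, xv, d, gv, fw$mu, fw$invstd)
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

# Layer normalization of a channel vector [C, N]: per column, per-channel affine.
op_layernorm_vec <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[1]
  mu <- colMeans(x$value)
  xc <- sweep(x$value, 2, mu)
  va <- colMeans(xc * xc)
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  val <- xhat * gamma$value + beta$value
  gv <- gamma$value
  ag_node(val, parents = list(x, gamma, beta), tape = tape, vjp = function(g) {
    dim(g) <- d
    dgamma <- rowSums(g * xhat)
    dbeta <- rowSums(g)
    dxhat <- g * gv
    a_n <- colMeans(dxhat)
    b_n <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(sweep(dxhat, 2, a_n), 1:2, xhat * rep(b_n, each = C)),
                2, invstd, `*`)
    list(dx, dgamma, dbeta)
  })
}

# ---- pointwise -----------------------------------------------------------

op_relu <- function(tape, x) {
  val <- cpp_relu_forward(x$value)
  ag_node(val, parents = list(x), tape = tape,
          vjp = function(g) list(cpp_relu_backward(g, val)))
}

op_sigmoid <- function(tape, x) {
  val <- x$value
  val[] <- stats::plogis(as.vector(x$value))
  ag_node(val, parents = list(x), tape = tape,
          vjp = function(g) list(g * val * (1 - val)))
}

op_add <- function(tape, a, b) {
  ag_node(a$value + b$value, parents = list(a, b), tape = tape,
          vjp = function(g) list(g, g))
}

op_mul <- function(tape, a, b) {
  av <- a$value
  bv <- b$value
  ag_node(av * bv, parents = list(a, b), tape = tape,
          vjp = function(g) list(g * bv, g * av))
}

# Gate an [H, W, C, N] map by a per-(channel, sample) weight matrix [C, N].
op_scale_channels <- function(tape, x, s) {
  d <- dim(x$value)
  sb <- bcast_cn(s$value, d)
  xv <- x$value
  ag_node(x$value * sb, parents = list(x, s), tape = tape, vjp = function(g) {
    dim(g) <- d
    list(g * sb, spatial_sum_cn(g * xv))
  })
}

# ---- pooling to vectors, linear maps ------------------------------------

op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  ag_node(spatial_sum_cn(x$value) / hw, parents = list(x), tape = tape,
          vjp = function(g) {
            gx <- rep(as.vector(g), each = hw) / hw
            dim(gx) <- d
            list(gx)
          })
}

op_flatten <- function(tape, x) {
  d <- dim(x$value)
  ag_node(matrix(x$value, d[1] * d[2] * d[3], d[4]), parents = list(x),
          tape = tape, vjp = function(g) {
            dim(g) <- d
            list(g)
          })
}

op_linear <- function(tape, x, w, b = NULL) {
  if (ncol(w$value) != nrow(x$value)) {
    stop(sprintf("linear layer expects %d input features, got %d",
                 ncol(w$value), nrow(x$value)), call. = FALSE)
  }
  val <- w$value %*% x$value
  if (!is.null(b)) val <- val + b$value
  xv <- x$value
  wv <- w$value
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(val, parents = parents, tape = tape, vjp = function(g) {
    dim(g) <- dim(val)
    out <- list(crossprod(wv, g), tcrossprod(g, xv))
    if (!is.null(b)) out <- c(out, list(rowSums(g)))
    out
  })
}

# Per-feature learnable scale of a [D, N] matrix (GAP-FC head).
op_scale_vec <- function(tape, x, s) {
  xv <- x$value
  sv <- s$value
  ag_node(xv * sv, parents = list(x, s), tape = tape,
          vjp = function(g) list(g * sv, rowSums(g * xv)))
}

# Per-channel bias of a feature map (1x1 conv bias).
op_bias_channel <- function(tape, x, b) {
  d <- dim(x$value)
  ag_node(x$value + bcast_c(b$value, d), parents = list(x, b), tape = tape,
          vjp = function(g) {
            dim(g) <- d
            list(g, rowSums(spatial_sum_cn(g)))
          })
}

# Per-position bias grid [H, W, K] added to an [H, W, K, N] map (C-GAP head).
# At non-native spatial sizes the grid is bilinearly resized (forward only).
op_posbias <- function(tape, x, b) {
  d <- dim(x$value)
  bv <- b$value
  native <- all(dim(bv)[1:2] == d[1:2])
  if (!native) bv <- resize_bilinear(bv, d[1], d[2])
  ag_node(x$value + rep(as.vector(bv), d[4]), parents = list(x, b),
          tape = tape, vjp = function(g) {
            if (!native) {
              stop("positional bias gradients are only defined at the native feature size",
                   call. = FALSE)
            }
            dim(g) <- d
            gb <- rowSums(matrix(g, d[1] * d[2] * d[3]))
            dim(gb) <- d[1:3]
            list(g, gb)
          })
}

# ---- loss ----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# Mean cross-entropy of logits [K, N] against integer labels in 1..K.
op_softmax_crossentropy <- function(tape, logits, labels) {
  p <- softmax_cols(logits$value)
  n <- ncol(p)
  picked <- p[cbind(labels, seq_len(n))]
  val <- -mean(log(pmax(picked, 1e-12)))
  ag_node(val, parents = list(logits), tape = tape, vjp = function(g) {
    gz <- p
    gz[cbind(labels, seq_len(n))] <- gz[cbind(labels, seq_len(n))] - 1
    list(gz * (g / n))
  })
}
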