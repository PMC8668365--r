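# Independent, loop-based reference implementations used as oracles.
# These deliberately share no code with the package internals.

ref_conv2d <- function(x, w, stride = 1, pad = 0) {
  d <- dim(x)
  wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  y <- array(0, c(Ho, Wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(wd[4])) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- 0
      for (c in seq_len(d[3])) for (kj in seq_len(wd[2])) for (ki in seq_len(wd[1])) {
        hi <- (ho - 1) * stride - pad + ki
        wi <- (wo - 1) * stride - pad + kj
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2]) {
          acc <- acc + x[hi, wi, c, n] * w[ki, kj, c, o]
        }
      }
      y[ho, wo, o, n] <- acc
    }
  }
  y
}

# layer norm of a single [H, W, C] map over all entries, per-channel affine
ref_layernorm_fm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- mean(x)
  va <- mean((x - mu)^2)
  xhat <- (x - mu) / sqrt(va + eps)
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- xhat[, , c] * gamma[c] + beta[c]
  out
}

ref_layernorm_vec <- function(v, gamma, beta, eps = 1e-5) {
  mu <- mean(v)
  va <- mean((v - mu)^2)
  (v - mu) / sqrt(va + eps) * gamma + beta
}

ref_relu <- function(x) pmax(x, 0)
ref_sigmoid <- function(x) 1 / (1 + exp(-x))
ref_gap <- function(x) apply(x, 3, mean)  # [H, W, C] -> length C

# straight-line composition of the CIIP residual bottleneck on one [H,W,C] map
ref_bottleneck <- function(x, pr) {
  p <- pr$params
  x4 <- array(x, c(dim(x), 1))
  h <- ref_conv2d(x4, p$w_reduce$value)
  h <- ref_relu(array(ref_layernorm_fm(array(h, dim(h)[1:3]), p$ln1$gamma$value,
                                       p$ln1$beta$value), dim(h)))
  h <- ref_conv2d(h, p$w_mid$value, stride = 1, pad = 1)
  h <- ref_relu(array(ref_layernorm_fm(array(h, dim(h)[1:3]), p$ln2$gamma$value,
                                       p$ln2$beta$value), dim(h)))
  h <- ref_conv2d(h, p$w_restore$value)
  h <- ref_relu(array(ref_layernorm_fm(array(h, dim(h)[1:3]), p$ln3$gamma$value,
                                       p$ln3$beta$value), dim(h)))
  x + array(h, dim(x))
}

# elementwise evaluation of the first-branch gate equations
ref_attention_first <- function(x) {
  g <- ref_gap(x)
  s <- ref_sigmoid(g)
  xp <- x
  for (c in seq_along(g)) xp[, , c] <- s[c] * x[, , c]
  list(output = xp, att = s * g)
}

# straight-line evaluation of the follow-up gate equations
ref_attention_followup <- function(x, att_prev, pr) {
  p <- pr$params
  a <- as.vector(p$fc_w$value %*% att_prev)
  a <- ref_relu(ref_layernorm_vec(a, p$fc_ln$gamma$value, p$fc_ln$beta$value))
  g <- ref_gap(x)
  z <- as.vector(p$att_w$value %*% (a + g))
  if (!is.null(p$att_ln)) {
    z <- ref_layernorm_vec(z, p$att_ln$gamma$value, p$att_ln$beta$value)
  }
  m <- ref_sigmoid(z)
  xp <- x
  for (c in seq_along(m)) xp[, , c] <- m[c] * x[, , c]
  list(output = xp, att = m * g, gate = m)
}

rel_diff <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-12)

# ---- image statistics ----------------------------------------------------

luminance <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)

# generator-aligned statistic: asymmetry of the luminance tails, positive
# for bright protrusions, negative for dark lesions
tail_asymmetry <- function(img) {
  q <- stats::quantile(luminance(img), c(0.01, 0.5, 0.99), names = FALSE)
  (q[3] - q[2]) - (q[2] - q[1])
}

local_contrast <- function(img) {
  l <- luminance(img)
  h <- nrow(l)
  w <- ncol(l)
  pad <- l[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) acc <- acc + pad[dy + seq_len(h), dx + seq_len(w)]
  mean(abs(l - acc / 9))
}

# ---- shared fixtures -----------------------------------------------------

# Small synthetic dataset reused across pipeline tests (built once per run).
tiny_dataset <- local({
  cache <- new.env()
  function(per_class, seed = 5, size = 64) {
    key <- paste(per_class, seed, size, collapse = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("iipnet_ds_", abs(seed),
                                         "_", paste(per_class, collapse = "_")))
      unlink(dir, recursive = TRUE)
      counts <- list(polyp = per_class, normal = per_class, others = per_class)
      cache[[key]] <- make_dataset(counts, seed = seed, size = size, out_dir = dir)
    }
    cache[[key]]
  }
})

# Accounting accessor: builds a variant, extracts the (small) complexity
# numbers, and discards the model immediately -- full backbones are several
# hundred MB of weight arrays, so they are never cached across tests.
variant_accounting <- local({
  cache <- new.env()
  function(depth, head = "FC", k = 3) {
    key <- paste(depth, head, k, sep = "_")
    if (is.null(cache[[key]])) {
      set.seed(depth + k)
      m <- build_model(model_spec(depth, head, k, 256))
      cache[[key]] <- list(
        layers = count_weight_layers(m),
        flops256 = count_flops(m, 256),
        flops224 = count_flops(m, 224),
        flops512 = count_flops(m, 512),
        report = complexity_report(m)
      )
      rm(m)
      gc(FALSE)
    }
    cache[[key]]
  }
})

# Independent closed-form multiply-add total for an FC-head variant at
# input side S: written as plain stage-by-stage arithmetic.
ref_flops_fc <- function(stage_blocks, S = 256, k = 3) {
  widths <- c(64, 128, 256, 512)
  couts <- c(256, 512, 1024, 2048)
  cins <- c(64, 256, 512, 1024)
  divs <- c(4, 8, 16, 32)
  total <- 7 * 7 * 3 * 64 * (S / 2)^2  # stem
  for (s in 1:4) {
    w <- widths[s]
    co <- couts[s]
    ci <- cins[s]
    div_in <- if (s == 1) divs[s] else divs[s] / 2
    first <- ci * w * (S / div_in)^2 + 9 * w * w * (S / divs[s])^2 +
      w * co * (S / divs[s])^2 + ci * co * (S / divs[s])^2
    rest <- (co * w + 9 * w * w + w * co) * (S / divs[s])^2
    total <- total + first + (stage_blocks[s] - 1) * rest
  }
  # CIIP blocks after stages 1-3, bottleneck reduction 4
  for (i in 1:3) {
    c0 <- couts[i]
    cr <- c0 / 4
    total <- total + (c0 * cr + 9 * cr * cr + cr * c0) * (S / divs[i])^2
    if (i > 1) total <- total + couts[i - 1] * c0 + c0 * c0  # fc_match + att_conv
  }
  total + (S / 32)^2 * 2048 * k  # FC head
}
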