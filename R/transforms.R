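# Image array utilities: bilinear resampling, rotation, flips and
# photometric jitter.  Images are numeric arrays [H, W, C] (C = 3 for RGB);
# intensity range is stated per function.

# Bilinear resize of an [H, W] or [H, W, C] array using half-pixel-center
# coordinate mapping.
resize_bilinear <- function(img, h_out, w_out) {
  d <- dim(img)
  h <- d[1]
  w <- d[2]
  nc <- if (length(d) == 3) d[3] else 1L
  if (h == h_out && w == w_out) return(img)
  sy <- (seq_len(h_out) - 0.5) * h / h_out - 0.5
  sx <- (seq_len(w_out) - 0.5) * w / w_out - 0.5
  r0 <- pmin(pmax(floor(sy), 0), h - 1)
  c0 <- pmin(pmax(floor(sx), 0), w - 1)
  r1 <- pmin(r0 + 1, h - 1)
  c1 <- pmin(c0 + 1, w - 1)
  wr <- pmin(pmax(sy - r0, 0), 1)
  wc <- pmin(pmax(sx - c0, 0), 1)
  out <- array(0, c(h_out, w_out, nc))
  im <- if (length(d) == 3) img else array(img, c(h, w, 1L))
  for (ch in seq_len(nc)) {
    p <- im[, , ch]
    a <- p[r0 + 1, c0 + 1, drop = FALSE]
    b <- p[r0 + 1, c1 + 1, drop = FALSE]
    cc <- p[r1 + 1, c0 + 1, drop = FALSE]
    dd <- p[r1 + 1, c1 + 1, drop = FALSE]
    top <- a + t(t(b - a) * wc)
    bot <- cc + t(t(dd - cc) * wc)
    out[, , ch] <- top + (bot - top) * wr
  }
  if (length(d) == 3) out else out[, , 1]
}

# Median colour of the one-pixel border, used as rotation fill.
median_border_colour <- function(img) {
  d <- dim(img)
  border <- rbind(
    matrix(img[c(1, d[1]), , ], ncol = d[3]),
    matrix(img[, c(1, d[2]), ], ncol = d[3])
  )
  apply(border, 2, stats::median)
}

# Rotate an RGB array about its centre by `angle` degrees (counterclockwise),
# bilinear interpolation, exposed corners filled with `fill` (per-channel).
# Output has the same dimensions as the input; angle 0 is the exact identity.
rotate_image <- function(img, angle, fill = median_border_colour(img)) {
  if (angle == 0) return(img)
  d <- dim(img)
  h <- d[1]
  w <- d[2]
  th <- angle * pi / 180
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  # inverse rotation of output pixel coordinates
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  sxf <- cos(th) * xx + sin(th) * yy + cx
  syf <- -sin(th) * xx + cos(th) * yy + cy
  valid <- sxf >= 1 & sxf <= w & syf >= 1 & syf <= h
  r0 <- pmin(pmax(floor(syf), 1), h - 1)
  c0 <- pmin(pmax(floor(sxf), 1), w - 1)
  wr <- pmin(pmax(syf - r0, 0), 1)
  wc <- pmin(pmax(sxf - c0, 0), 1)
  i00 <- r0 + h * (c0 - 1)
  i01 <- r0 + h * c0
  i10 <- r0 + 1 + h * (c0 - 1)
  i11 <- r0 + 1 + h * c0
  out <- img
  for (ch in seq_len(d[3])) {
    p <- img[, , ch]
    v <- (1 - wr) * ((1 - wc) * p[i00] + wc * p[i01]) +
      wr * ((1 - wc) * p[i10] + wc * p[i11])
    v[!valid] <- fill[ch]
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

flip_horizontal <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_vertical <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

# Multiplicative brightness / mean-anchored contrast on a [0, maxval] image.
adjust_brightness <- function(img, factor, maxval = 255) {
  pmin(pmax(img * factor, 0), maxval)
}

adjust_contrast <- function(img, factor, maxval = 255) {
  m <- mean(img)
  pmin(pmax((img - m) * factor + m, 0), maxval)
}
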