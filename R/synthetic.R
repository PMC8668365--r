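# Synthetic colonoscopy-like image generator.
#
# Images emulate the class structure of colonoscopy datasets: a mucosa-toned
# base with vignette, folds and vessels; polyps add bright elliptical
# protrusions with a specular highlight and a shadowed rim; ulcerative
# colitis adds many unevenly distributed pale ulcer speckles; "others" adds
# one large irregular flat dark lesion.  Everything is deterministic given
# (recipe, seed, size).

iipnet_labels <- c("polyp", "normal", "others", "ulcerative_colitis")

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Rendering recipe for one image class
#'
#' Bundles the bounded geometry and palette parameters the generator draws
#' from: mucosa base colour ranges, vignette strength, fold/vessel counts,
#' and the class-specific lesion geometry (protrusion radii for polyps,
#' speckle density for ulcerative colitis, lesion size for other lesions).
#'
#' @param label one of `"polyp"`, `"normal"`, `"others"`,
#'   `"ulcerative_colitis"`.
#' @return a `class_recipe` list of parameter ranges.
#' @export
class_recipe <- function(label) {
  label <- match.arg(label, iipnet_labels)
  base <- list(
    label = label,
    base_r = c(0.73, 0.78), base_g = c(0.44, 0.49), base_b = c(0.40, 0.45),
    texture_amp = c(0.015, 0.035),
    vignette = 0.18,
    fold_count = c(2L, 4L), fold_dark = 0.05,
    vessel_count = c(4L, 8L), vessel_dark = 0.06,
    roughness = 0.01
  )
  extra <- switch(label,
    polyp = list(n_protrusions = c(1L, 2L), radius_frac = c(0.13, 0.20),
                 dome_gain = 0.20, highlight = 0.98, rim_dark = 0.06),
    ulcerative_colitis = list(n_speckles = c(8L, 18L),
                              speckle_radius_frac = c(0.025, 0.055),
                              speckle_rgb = c(0.93, 0.88, 0.78)),
    others = list(lesion_radius_frac = c(0.20, 0.30), lesion_blend = 0.85,
                  lesion_rough = 0.04,
                  lesion_rgb = c(0.38, 0.22, 0.20)),
    normal = list()
  )
  structure(c(base, extra), class = "class_recipe")
}

# 3x3 box blur with replicated edges.
box_blur3 <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  pad <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + pad[dy + seq_len(h), dx + seq_len(w)]
  }
  acc / 9
}

#' Generate one synthetic colonoscopy-like image
#'
#' Deterministic given `(recipe, seed, size)`: the same call returns a
#' pixel-identical image.
#'
#' @param recipe a [class_recipe()].
#' @param seed integer seed for this image.
#' @param size image side in pixels, at least 64.
#' @return a `size x size x 3` numeric array with integer values in
#'   `[0, 255]`.
#' @export
generate_image <- function(recipe, seed, size = 256) {
  if (size < 64) stop("size must be at least 64", call. = FALSE)
  with_seed(seed, {
    u <- matrix(rep((seq_len(size) - 0.5) / size, each = size), size, size)
    v <- matrix((seq_len(size) - 0.5) / size, size, size)
    runif_r <- function(range) stats::runif(1, range[1], range[2])
    rint <- function(range) sample(seq(range[1], range[2]), 1)

    base_rgb <- c(runif_r(recipe$base_r), runif_r(recipe$base_g),
                  runif_r(recipe$base_b))

    # smooth low-frequency mucosa texture
    tex <- matrix(0, size, size)
    for (i in 1:3) {
      amp <- runif_r(recipe$texture_amp)
      fx <- stats::runif(1, 0.8, 3)
      fy <- stats::runif(1, 0.8, 3)
      ph <- stats::runif(1, 0, 2 * pi)
      tex <- tex + amp * sin(2 * pi * (fx * u + fy * v) + ph)
    }

    # radial vignette
    r2 <- (u - 0.5)^2 + (v - 0.5)^2
    vig <- 1 - recipe$vignette * (r2 / 0.5)

    # broad dark folds (soft ridges along random directions)
    shade <- matrix(0, size, size)
    for (i in seq_len(rint(recipe$fold_count))) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0.15, 0.85)
      wdt <- stats::runif(1, 0.02, 0.05)
      proj <- u * cos(th) + v * sin(th)
      shade <- shade + recipe$fold_dark * exp(-(proj - off)^2 / (2 * wdt^2))
    }

    # thin darker vessels: jittered random walks rasterised onto a mask
    vmask <- matrix(0, size, size)
    for (i in seq_len(rint(recipe$vessel_count))) {
      y <- stats::runif(1, 1, size)
      x <- stats::runif(1, 1, size)
      th <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(70)) {
        th <- th + stats::rnorm(1, 0, 0.25)
        y <- y + 1.3 * sin(th)
        x <- x + 1.3 * cos(th)
        if (y < 1 || y > size || x < 1 || x > size) break
        vmask[round(y), round(x)] <- 1
      }
    }
    vmask <- box_blur3(vmask)
    shade <- shade + recipe$vessel_dark * vmask / max(max(vmask), 1e-9)

    lum_shift <- tex - shade +
      matrix(stats::rnorm(size * size, 0, recipe$roughness), size, size)

    img <- array(0, c(size, size, 3))
    for (ch in 1:3) img[, , ch] <- (base_rgb[ch] + lum_shift) * vig

    lbl <- recipe$label
    if (lbl == "polyp") {
      for (i in seq_len(rint(recipe$n_protrusions))) {
        cy <- stats::runif(1, 0.30, 0.70)
        cx <- stats::runif(1, 0.30, 0.70)
        rx <- runif_r(recipe$radius_frac)
        ry <- rx * stats::runif(1, 0.75, 1.3)
        th <- stats::runif(1, 0, pi)
        du <- u - cx
        dv <- v - cy
        a <- du * cos(th) + dv * sin(th)
        b <- -du * sin(th) + dv * cos(th)
        rho <- sqrt((a / rx)^2 + (b / ry)^2)
        dome <- ifelse(rho < 1, cos(pmin(rho, 1) * pi / 2)^1.5, 0)
        rim <- exp(-((rho - 1.12) / 0.08)^2)
        hl <- exp(-(((du + 0.30 * rx)^2 + (dv + 0.30 * ry)^2)) /
                    (2 * (0.16 * rx)^2))
        for (ch in 1:3) {
          p <- img[, , ch]
          p <- p + recipe$dome_gain * dome * c(1.05, 0.95, 0.9)[ch]
          p <- p - recipe$rim_dark * rim
          p <- p + (recipe$highlight - p) * hl
          img[, , ch] <- p
        }
      }
    } else if (lbl == "ulcerative_colitis") {
      nclust <- sample(1:2, 1)
      centers <- cbind(stats::runif(nclust, 0.3, 0.7),
                       stats::runif(nclust, 0.3, 0.7))
      for (i in seq_len(rint(recipe$n_speckles))) {
        cl <- centers[sample(nclust, 1), ]
        cy <- min(max(cl[1] + stats::rnorm(1, 0, 0.13), 0.08), 0.92)
        cx <- min(max(cl[2] + stats::rnorm(1, 0, 0.13), 0.08), 0.92)
        rr <- runif_r(recipe$speckle_radius_frac)
        d2 <- ((u - cx)^2 + (v - cy)^2) / rr^2
        ragged <- 1 + 0.5 * sin(2 * pi * (stats::runif(1, 1, 3) * u +
                                            stats::runif(1, 1, 3) * v) +
                                  stats::runif(1, 0, 2 * pi))
        mask <- pmin(exp(-d2) * ragged, 1)
        for (ch in 1:3) {
          img[, , ch] <- img[, , ch] +
            0.85 * mask * (recipe$speckle_rgb[ch] - img[, , ch])
        }
      }
    } else if (lbl == "others") {
      cy <- stats::runif(1, 0.35, 0.65)
      cx <- stats::runif(1, 0.35, 0.65)
      r0 <- runif_r(recipe$lesion_radius_frac)
      phase <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(3, 0.05, 0.15)
      ang <- atan2(v - cy, u - cx)
      rb <- r0 * (1 + amp[1] * cos(ang + phase[1]) +
                    amp[2] * cos(2 * ang + phase[2]) +
                    amp[3] * cos(3 * ang + phase[3]))
      d <- sqrt((u - cx)^2 + (v - cy)^2)
      mask <- stats::plogis((rb - d) / 0.015)
      rough <- box_blur3(matrix(stats::rnorm(size * size, 0,
                                             recipe$lesion_rough), size, size))
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] +
          mask * (recipe$lesion_blend * (recipe$lesion_rgb[ch] - img[, , ch]) + rough)
      }
    }

    round(pmin(pmax(img, 0), 1) * 255)
  })
}

# ---- augmentation --------------------------------------------------------

#' Draw a seeded set of augmentation parameters
#'
#' Random horizontal flip (p = 0.5), random vertical flip (p = 0.5),
#' rotation uniform in \[-90, +90\] degrees, and multiplicative brightness
#' and contrast factors uniform in \[0.8, 1.2\].
#'
#' @param seed integer seed.
#' @return a named list `hflip, vflip, angle, brightness, contrast`.
#' @export
augmentation_params <- function(seed) {
  with_seed(seed, list(
    hflip = stats::runif(1) < 0.5,
    vflip = stats::runif(1) < 0.5,
    angle = stats::runif(1, -90, 90),
    brightness = stats::runif(1, 0.8, 1.2),
    contrast = stats::runif(1, 0.8, 1.2)
  ))
}

#' Apply augmentation with explicit parameters
#'
#' Order: flips, rotation (exposed corners filled with the image's median
#' border colour), brightness, contrast.  With flips off, angle 0 and unit
#' factors this is the exact identity.
#'
#' @param image an `[H, W, 3]` array in `[0, 255]`.
#' @param params a list as returned by [augmentation_params()].
#' @return an array of the same dimensions.
#' @export
apply_augmentation <- function(image, params) {
  out <- image
  if (isTRUE(params$hflip)) out <- flip_horizontal(out)
  if (isTRUE(params$vflip)) out <- flip_vertical(out)
  if (params$angle != 0) out <- rotate_image(out, params$angle)
  if (params$brightness != 1) out <- adjust_brightness(out, params$brightness)
  if (params$contrast != 1) out <- adjust_contrast(out, params$contrast)
  out
}

#' Seeded random augmentation
#'
#' @inheritParams apply_augmentation
#' @param seed integer seed; the same (image, seed) pair always returns the
#'   same augmented image.
#' @export
augment <- function(image, seed) {
  apply_augmentation(image, augmentation_params(seed))
}

# ---- manifests -----------------------------------------------------------

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes PNG images under `out_dir/<split>/<label>/` and a manifest CSV;
#' deterministic given `seed`.
#'
#' @param per_class_counts named list mapping each label to
#'   `c(train_n, test_n)` (all counts >= 1).
#' @param seed master seed; per-image seeds are derived from it.
#' @param size image side in pixels.
#' @param out_dir output directory (created if needed).
#' @return the manifest: a tibble with columns `path` (relative to
#'   `out_dir`), `label`, `split`, `seed`, `aug_seed` (NA marks original
#'   images).  Written alongside the images as `manifest.csv`.
#' @export
make_dataset <- function(per_class_counts, seed = 1, size = 64, out_dir) {
  labels <- names(per_class_counts)
  if (is.null(labels) || !all(labels %in% iipnet_labels)) {
    stop("per_class_counts must be named with labels among: ",
         paste(iipnet_labels, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(vapply(per_class_counts, function(x) all(x >= 1), logical(1))))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory \"%s\"", out_dir), call. = FALSE)
  }
  rows <- list()
  i <- 0L
  for (lbl in labels) {
    recipe <- class_recipe(lbl)
    counts <- per_class_counts[[lbl]]
    for (split in c("train", "test")) {
      n <- counts[if (split == "train") 1 else 2]
      dir.create(file.path(out_dir, split, lbl), recursive = TRUE,
                 showWarnings = FALSE)
      for (j in seq_len(n)) {
        i <- i + 1L
        img_seed <- derive_seed(seed, i)
        rel <- file.path(split, lbl, sprintf("%s_%04d.png", lbl, j))
        img <- generate_image(recipe, img_seed, size)
        png::writePNG(img / 255, file.path(out_dir, rel))
        rows[[i]] <- tibble::tibble(path = rel, label = lbl, split = split,
                                    seed = img_seed, aug_seed = NA_integer_)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "augmentation_factor") <- 1L
  manifest
}

#' Read a manifest CSV written by [make_dataset()]
#'
#' @param path path to the manifest CSV; the directory containing it
#'   becomes the dataset root.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: \"%s\"", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  manifest <- tibble::as_tibble(df)
  manifest$aug_seed <- as.integer(manifest$aug_seed)
  attr(manifest, "out_dir") <- dirname(path)
  manifest
}

#' Expand a manifest with augmented copies
#'
#' Pure bookkeeping: each original row is kept (marked by `aug_seed = NA`)
#' and `factor - 1` augmented copies with distinct derived augmentation
#' seeds are appended, preserving split membership, so the returned
#' manifest has exactly `factor` times as many rows.  Augmentation is
#' applied on the fly when images are loaded.
#'
#' @param manifest a dataset manifest.
#' @param factor total expansion factor, at least 1.
#' @export
expand_dataset <- function(manifest, factor) {
  if (factor < 1) stop("expansion factor must be at least 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(manifest)
  copies <- lapply(seq_len(factor - 1L), function(j) {
    cp <- manifest
    cp$aug_seed <- vapply(seq_len(nrow(manifest)),
                          function(i) derive_seed(manifest$seed[i] + j, i),
                          integer(1))
    cp
  })
  out <- dplyr::bind_rows(c(list(manifest), copies))
  attr(out, "out_dir") <- attr(manifest, "out_dir")
  attr(out, "augmentation_factor") <-
    (attr(manifest, "augmentation_factor") %||% 1L) * factor
  out
}

#' @importFrom rlang %||%
NULL
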