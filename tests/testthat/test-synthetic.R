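# Synthetic image generator and augmentation stack: determinism, range
# contracts, class separability, and manifest bookkeeping.

test_that("image generation is deterministic and honours the range contract", {
  for (lbl in c("polyp", "normal", "others", "ulcerative_colitis")) {
    r <- class_recipe(lbl)
    a <- generate_image(r, seed = 42, size = 64)
    b <- generate_image(r, seed = 42, size = 64)
    expect_identical(a, b)
    expect_identical(dim(a), c(64L, 64L, 3L))
    expect_true(all(a >= 0 & a <= 255))
    expect_true(all(a == round(a)))
    c1 <- generate_image(r, seed = 43, size = 64)
    expect_gt(max(abs(c1 - a)), 0)  # different seeds differ
  }
  expect_error(generate_image(class_recipe("normal"), 1, size = 32), "at least 64")
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(7)
  before <- rnorm(3)
  set.seed(7)
  invisible(generate_image(class_recipe("polyp"), 99, 64))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("polyp images show higher local contrast than normal images", {
  n <- 200
  polyp <- vapply(seq_len(n), function(i) {
    local_contrast(generate_image(class_recipe("polyp"), 2000 + i, 64))
  }, numeric(1))
  normal <- vapply(seq_len(n), function(i) {
    local_contrast(generate_image(class_recipe("normal"), 2000 + i, 64))
  }, numeric(1))
  expect_gt(mean(polyp), mean(normal))
})

test_that("a single-statistic threshold classifier separates the three classes", {
  classes <- c("others", "normal", "polyp")  # ordered by the statistic
  stat_for <- function(lbl, seeds) {
    r <- class_recipe(lbl)
    vapply(seeds, function(s) tail_asymmetry(generate_image(r, s, 64)), numeric(1))
  }
  train <- lapply(classes, stat_for, seeds = 3000 + 1:40)
  centers <- vapply(train, mean, numeric(1))
  cuts <- (centers[-1] + centers[-3]) / 2
  test <- lapply(classes, stat_for, seeds = 4000 + 1:30)
  pred <- lapply(test, function(v) classes[findInterval(v, cuts) + 1])
  acc <- mean(unlist(Map(function(p, cl) p == cl, pred, classes)))
  expect_gt(acc, 0.70)
})

test_that("augmentation with explicit null parameters is the identity", {
  img <- generate_image(class_recipe("normal"), 5, 64)
  id <- list(hflip = FALSE, vflip = FALSE, angle = 0, brightness = 1, contrast = 1)
  expect_identical(apply_augmentation(img, id), img)
})

test_that("a horizontal flip applied twice restores the image exactly", {
  img <- generate_image(class_recipe("polyp"), 6, 64)
  pars <- list(hflip = TRUE, vflip = FALSE, angle = 0, brightness = 1, contrast = 1)
  once <- apply_augmentation(img, pars)
  expect_gt(max(abs(once - img)), 0)
  expect_identical(apply_augmentation(once, pars), img)
})

test_that("seeded augmentation is deterministic with calibrated flip rates", {
  img <- generate_image(class_recipe("normal"), 7, 64)
  expect_identical(augment(img, 11), augment(img, 11))
  pars <- lapply(1:1000, augmentation_params)
  hrate <- mean(vapply(pars, `[[`, logical(1), "hflip"))
  vrate <- mean(vapply(pars, `[[`, logical(1), "vflip"))
  expect_gte(hrate, 0.45)
  expect_lte(hrate, 0.55)
  expect_gte(vrate, 0.45)
  expect_lte(vrate, 0.55)
  angles <- vapply(pars, `[[`, numeric(1), "angle")
  expect_true(all(angles >= -90 & angles <= 90))
  bright <- vapply(pars, `[[`, numeric(1), "brightness")
  expect_true(all(bright >= 0.8 & bright <= 1.2))
})

test_that("rotation fills exposed corners with the median border colour", {
  img <- array(100, c(64, 64, 3))
  img[, , 1] <- 200  # uniform colour, so rotation must preserve it exactly
  rot <- iipnet:::rotate_image(img, 45)
  expect_equal(rot[1, 1, ], c(200, 100, 100))
  expect_identical(dim(rot), dim(img))
})

test_that("expand_dataset performs the published x5 bookkeeping", {
  big <- tibble::tibble(
    path = sprintf("train/x/%05d.png", 1:22809),
    label = "normal", split = rep(c("train", "test"), c(17009, 5800)),
    seed = 1:22809, aug_seed = NA_integer_
  )
  out <- expand_dataset(big, 5)
  expect_identical(nrow(out), 114045L)
  expect_identical(sum(is.na(out$aug_seed)), 22809L)
  expect_identical(table(out$split)[["train"]], 17009L * 5L)

  small <- big[1:10, ]
  expect_identical(expand_dataset(small, 1), small)
  out3 <- expand_dataset(small, 3)
  expect_identical(nrow(out3), 30L)
  expect_identical(sum(is.na(out3$aug_seed)), 10L)
  expect_false(any(duplicated(stats::na.omit(out3$aug_seed))))
  expect_identical(out3$label, rep(small$label, 3))  # labels never change
  expect_error(expand_dataset(small, 0), "at least 1")
})

test_that("make_dataset writes a deterministic manifest with exact proportions", {
  counts <- list(polyp = c(3, 1), normal = c(11, 4), others = c(3, 1))
  d1 <- file.path(tempdir(), "mk1")
  d2 <- file.path(tempdir(), "mk2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_dataset(counts, seed = 9, size = 64, out_dir = d1)
  m2 <- make_dataset(counts, seed = 9, size = 64, out_dir = d2)
  expect_identical(nrow(m1), 23L)
  expect_identical(unname(lapply(m1, identity)), unname(lapply(m2, identity)))  # columns only
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e5),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e5))
  # images themselves are byte-identical across same-seed runs
  expect_identical(readBin(file.path(d1, m1$path[1]), "raw", 1e5),
                   readBin(file.path(d2, m1$path[1]), "raw", 1e5))
  expect_identical(sort(unique(m1$label)), sort(c("polyp", "normal", "others")))
  expect_false(any(duplicated(m1$path)))
  expect_identical(table(m1$label, m1$split)["normal", "train"], 11L)
  # manifest round-trips through its CSV
  m1b <- read_manifest(file.path(d1, "manifest.csv"))
  expect_identical(unname(lapply(m1b, identity)), unname(lapply(m1, identity)))
})

test_that("the scaled Dataset-A preset yields 228 images in the source ratios", {
  counts <- list(polyp = c(30, 10), normal = c(110, 38), others = c(30, 10))
  expect_identical(sum(unlist(counts)), 228)
  # proportions within one image of 4002/14801/4006 out of 22809, scaled /100
  scaled <- unlist(lapply(counts, sum)) / 228
  orig <- c(polyp = 4002, normal = 14801, others = 4006) / 22809
  expect_true(all(abs(scaled - orig) * 228 <= 1))
})
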