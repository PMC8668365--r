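# CIIP block: residual bottleneck, the two attention branches and their
# dispatch, checked against independent loop-based evaluations of the
# gating equations.

test_that("bottleneck short connection preserves shape and reduces to the identity", {
  set.seed(101)
  pr <- ciip_params(8, reduction = 4)
  x <- array(rnorm(8 * 4 * 4), c(4, 4, 8))
  expect_identical(dim(bottleneck_short_connection(x, pr)), dim(x))

  # zero convolution weights make the residual branch vanish
  for (nm in c("w_reduce", "w_mid", "w_restore")) pr$params[[nm]]$value[] <- 0
  expect_equal(bottleneck_short_connection(x, pr), x)

  bad <- array(rnorm(6 * 4 * 4), c(4, 4, 6))
  expect_error(bottleneck_short_connection(bad, pr), "6 channels.*expects 8")
})

test_that("bottleneck short connection matches a straight-line reference composition", {
  set.seed(102)
  for (i in 1:5) {
    pr <- ciip_params(8, reduction = 4)
    x <- array(rnorm(8 * 4 * 4), c(4, 4, 8))
    expect_lt(rel_diff(bottleneck_short_connection(x, pr),
                       ref_bottleneck(x, pr)), 1e-10)
  }
})

test_that("first-branch attention follows the sigmoid-gated pooling equations", {
  # zero input is absorbed
  z <- array(0, c(4, 4, 8))
  res <- attention_first(z)
  expect_true(all(res$output == 0))
  expect_true(all(res$att == 0))

  # constant channel closed form: s = sigmoid(v), output = s*v, att = s*v
  x <- array(0, c(3, 3, 2))
  x[, , 1] <- 1.7
  x[, , 2] <- -0.4
  res <- attention_first(x)
  for (c in 1:2) {
    v <- x[1, 1, c]
    expect_equal(res$output[, , c], matrix(plogis(v) * v, 3, 3))
    expect_equal(res$att[c], plogis(v) * v)
  }

  # random maps against the elementwise oracle
  set.seed(103)
  for (i in 1:10) {
    x <- array(rnorm(4 * 3 * 3), c(3, 3, 4))
    res <- attention_first(x)
    ref <- ref_attention_first(x)
    expect_lt(rel_diff(res$output, ref$output), 1e-12)
    expect_lt(rel_diff(res$att, ref$att), 1e-12)
  }
})

test_that("follow-up attention matches the straight-line reference and degenerates correctly", {
  set.seed(104)
  # zero feature map is absorbed regardless of the incoming attention
  pr <- ciip_params(6, prev_channels = 4, reduction = 2)
  res <- attention_followup(array(0, c(3, 3, 6)), rnorm(4), pr)
  expect_true(all(res$output == 0))
  expect_true(all(res$att == 0))

  # with a silent attention path and a pass-through attention convolution,
  # the gate reduces to the first-branch sigmoid
  pr0 <- ciip_params(6, prev_channels = 4, reduction = 2, att_norm = FALSE)
  pr0$params$fc_w$value[] <- 0
  pr0$params$att_w$value <- diag(6)
  x <- array(rnorm(6 * 3 * 3), c(3, 3, 6))
  expect_equal(attention_followup(x, rnorm(4), pr0)$output,
               attention_first(x)$output)

  # random cases against the straight-line oracle
  for (i in 1:10) {
    pr <- ciip_params(6, prev_channels = 4, reduction = 2)
    x <- array(rnorm(6 * 3 * 3), c(3, 3, 6))
    att1 <- rnorm(4)
    res <- attention_followup(x, att1, pr)
    ref <- ref_attention_followup(x, att1, pr)
    expect_lt(rel_diff(res$output, ref$output), 1e-10)
    expect_lt(rel_diff(res$att, ref$att), 1e-10)
  }

  # shape errors name the offending sizes
  pr <- ciip_params(6, prev_channels = 4, reduction = 2)
  expect_error(attention_followup(x, rnorm(5), pr), "length 5.*expects 4")
  pr1 <- ciip_params(6, reduction = 2)  # first-branch block: no attention parameters
  expect_error(attention_followup(x, rnorm(4), pr1), "without fc_match")
})

test_that("ciip_forward dispatches on the presence of incoming attention", {
  set.seed(105)
  pr1 <- ciip_params(8)
  pr2 <- ciip_params(8, prev_channels = 8)
  x <- array(rnorm(8 * 4 * 4), c(4, 4, 8))

  r1 <- ciip_forward(x, NULL, pr1)
  manual1 <- attention_first(bottleneck_short_connection(x, pr1))
  expect_equal(r1$output, manual1$output)
  expect_equal(r1$att, manual1$att)

  att1 <- rnorm(8)
  r2 <- ciip_forward(x, att1, pr2)
  manual2 <- attention_followup(bottleneck_short_connection(x, pr2), att1, pr2)
  expect_equal(r2$output, manual2$output)
  expect_equal(r2$att, manual2$att)
})

test_that("chained CIIP blocks feed attention forward between modules", {
  set.seed(106)
  prA <- ciip_params(4)
  prB <- ciip_params(4, prev_channels = 4)
  prC <- ciip_params(4, prev_channels = 4)
  x <- array(rnorm(4 * 5 * 5), c(5, 5, 4))

  a <- ciip_forward(x, NULL, prA)
  b <- ciip_forward(a$output, a$att, prB)
  c3 <- ciip_forward(b$output, b$att, prC)
  expect_length(c3$att, 4)

  # the second block really consumes the first block's attention: changing
  # only the incoming attention changes the second block's output
  b_alt <- ciip_forward(a$output, a$att + 1, prB)
  expect_gt(max(abs(b_alt$output - b$output)), 0)

  # and matches an explicit straight-line recomputation of the whole chain
  hB <- bottleneck_short_connection(a$output, prB)
  refB <- ref_attention_followup(hB, a$att, prB)
  expect_lt(rel_diff(b$output, refB$output), 1e-10)
  expect_lt(rel_diff(b$att, refB$att), 1e-10)
})

test_that("both branches satisfy the gate invariants on many random inputs", {
  set.seed(107)
  worst <- 0
  for (i in 1:60) {
    ch <- sample(c(4L, 6L, 8L), 1)
    hw <- sample(2:4, 1)
    x <- array(rnorm(ch * hw * hw, sd = runif(1, 0.5, 2)), c(hw, hw, ch))
    res <- attention_first(x)
    ref <- ref_attention_first(x)
    worst <- max(worst, rel_diff(res$output, ref$output),
                 rel_diff(res$att, ref$att))
    s <- plogis(apply(x, 3, mean))
    expect_true(all(s > 0 & s < 1))
  }
  for (i in 1:60) {
    ch <- sample(c(4L, 6L), 1)
    prev <- sample(c(3L, 5L), 1)
    hw <- sample(2:4, 1)
    pr <- ciip_params(ch, prev_channels = prev, reduction = 2)
    x <- array(rnorm(ch * hw * hw), c(hw, hw, ch))
    att1 <- rnorm(prev)
    res <- attention_followup(x, att1, pr)
    ref <- ref_attention_followup(x, att1, pr)
    worst <- max(worst, rel_diff(res$output, ref$output),
                 rel_diff(res$att, ref$att))
    expect_true(all(ref$gate > 0 & ref$gate < 1))
  }
  expect_lt(worst, 1e-5)
})

test_that("first-branch blocks serialize no attention parameters", {
  set.seed(108)
  v1 <- ciip_params_values(ciip_params(8))
  expect_false(any(grepl("fc|att", names(v1))))
  v2 <- ciip_params_values(ciip_params(8, prev_channels = 4))
  expect_true(any(grepl("fc_match", names(v2))))
  expect_true(any(grepl("att_conv", names(v2))))
})

test_that("ciip_params enforces the reduction-ratio divisibility precondition", {
  expect_error(ciip_params(6, reduction = 4), "divisible")
  expect_silent(ciip_params(6, reduction = 2))
})
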