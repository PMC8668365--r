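# One-vs-rest metric suite: confusion-matrix bookkeeping, the published
# worked examples, and algebraic identities.

test_that("confusion matrix uses the predicted-row convention", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(unclass(cm),
                   matrix(c(1L, 1L, 0L, 1L), 2, 2,
                          dimnames = list(predicted = c("A", "B"),
                                          actual = c("A", "B"))))
  # perfect prediction: diagonal with column sums equal to class supports
  y <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  cmd <- confusion_matrix(y, y, c("A", "B", "C"))
  expect_identical(diag(cmd), c(A = 5L, B = 3L, C = 2L))
  expect_identical(sum(cmd) - sum(diag(cmd)), 0L)

  expect_error(confusion_matrix(c("A", "D"), c("A", "A"), c("A", "B")), "D")
  expect_error(confusion_matrix(c("A"), c("A", "B")), "equal length")
})

test_that("matrix total is conserved under random labelings", {
  set.seed(401)
  for (i in 1:20) {
    yt <- sample(c("a", "b", "c"), 1000, replace = TRUE)
    yp <- sample(c("a", "b", "c"), 1000, replace = TRUE)
    cm <- confusion_matrix(yt, yp, c("a", "b", "c"))
    expect_identical(sum(cm), 1000L)
    # one-vs-rest counts always partition the total
    for (cl in c("a", "b", "c")) {
      expect_identical(sum(one_vs_rest(cm, cl)), 1000L)
    }
  }
})

test_that("one_vs_rest reduces hand-counted matrices correctly", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(one_vs_rest(cm, "A"), c(TP = 1L, FP = 0L, FN = 1L, TN = 1L))
  # diagonal matrix: no false positives or negatives anywhere
  y <- rep(c("A", "B", "C"), 4)
  cmd <- confusion_matrix(y, y, c("A", "B", "C"))
  for (cl in c("A", "B", "C")) {
    counts <- one_vs_rest(cmd, cl)
    expect_identical(unname(counts[c("FP", "FN")]), c(0L, 0L))
  }
  expect_error(one_vs_rest(cm, "Z"), "unknown class")
})

test_that("metric rows reproduce the published precision/recall -> F1 examples", {
  # published 3-class rows: (precision, recall) -> F1
  row1 <- metric_row(9460, 9460 / 94.88 * 100 - 9460, 9460 / 94.60 * 100 - 9460, 1e6)
  expect_equal(iipnet:::round_half_up(row1$f1), 94.74)
  # direct check on the F1 formula at the printed precisions
  f1 <- function(p, r) 2 * r * p / (r + p)
  expect_equal(iipnet:::round_half_up(f1(94.88, 94.60)), 94.74)
  expect_equal(iipnet:::round_half_up(f1(97.24, 95.00)), 96.11)
  # symmetric case: F1 equals the common value
  expect_equal(f1(87.3, 87.3), 87.3)
})

test_that("metric rows stay within bounds and handle undefined cells", {
  set.seed(402)
  for (i in 1:50) {
    counts <- as.integer(sample(0:50, 4, replace = TRUE)) + c(1L, 0L, 1L, 1L)
    row <- metric_row(counts[1], counts[2], counts[3], counts[4])
    vals <- unlist(row)
    expect_true(all(vals >= 0 & vals <= 100, na.rm = TRUE))
    expect_gte(row$f1 + 1e-9, min(row$precision, row$recall))
    expect_lte(row$f1 - 1e-9, max(row$precision, row$recall))
    expect_identical(row$class_accuracy, row$precision)
  }
  # zero predicted positives: precision is undefined, not 0 or 100
  row0 <- metric_row(0, 0, 5, 10)
  expect_true(is.na(row0$precision))
  expect_true(is.na(row0$class_accuracy))
  expect_identical(row0$recall, 0)
})

test_that("macro averages reproduce the published 4-class Average row", {
  acc <- c(100, 98.60, 88.83, 87.14)
  rec <- c(100, 98.60, 88.83, 93.64)
  spe <- c(100, 98.14, 95.25, 97.88)
  rows <- tibble::tibble(class = c("polyp", "normal", "others", "uc"),
                         class_accuracy = acc, recall = rec, specificity = spe)
  avg <- macro_average(rows)
  expect_identical(avg$class[1], "Average")
  expect_equal(iipnet:::round_half_up(avg$class_accuracy), 93.64)
  expect_equal(iipnet:::round_half_up(avg$recall), 95.27)
  expect_equal(iipnet:::round_half_up(avg$specificity), 97.82)
  # identity on a single row; invariance under row permutation
  one <- rows[2, ]
  expect_equal(macro_average(one)$recall, one$recall)
  expect_equal(macro_average(rows[sample(4), ])$recall, avg$recall)
  expect_error(macro_average(rows[0, ]), "at least one")
})

test_that("overall accuracy equals the support-weighted mean of recalls", {
  # published 3-class recalls and test supports give the headline accuracy
  rec <- c(99.40, 99.79, 99.00)
  sup <- c(1000, 3800, 1000)
  expect_equal(iipnet:::round_half_up(sum(rec * sup) / sum(sup)), 99.59)

  set.seed(403)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cm <- iipnet:::new_cm(matrix(rpois(k * k, 20), k, k,
                                 dimnames = list(letters[1:k], letters[1:k])))
    recalls <- vapply(rownames(cm), function(cl) {
      counts <- one_vs_rest(cm, cl)
      100 * counts["TP"] / (counts["TP"] + counts["FN"])
    }, numeric(1))
    supports <- colSums(cm)
    expect_equal(overall_accuracy(cm),
                 sum(recalls * supports) / sum(supports))
  }
  diag_cm <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_identical(overall_accuracy(diag_cm), 100)
})

test_that("uniform random predictions give chance-level overall accuracy", {
  set.seed(404)
  yt <- sample(c("a", "b", "c"), 30000, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 30000, replace = TRUE)
  acc <- overall_accuracy(confusion_matrix(yt, yp, c("a", "b", "c")))
  expect_gt(acc, 100 / 3 - 1)
  expect_lt(acc, 100 / 3 + 1)
})

test_that("binary one-vs-rest metrics equal the textbook binary definitions", {
  cm <- iipnet:::new_cm(matrix(c(40L, 10L, 5L, 45L), 2, 2,
                               dimnames = list(c("pos", "neg"), c("pos", "neg"))))
  counts <- one_vs_rest(cm, "pos")
  row <- metric_row(counts["TP"], counts["FP"], counts["FN"], counts["TN"])
  expect_equal(row$precision, 100 * 40 / 45)
  expect_equal(row$recall, 100 * 40 / 50)
  expect_equal(row$specificity, 100 * 45 / 50)
})

test_that("class_metrics builds the per-class table with an Average row", {
  set.seed(405)
  yt <- sample(c("polyp", "normal", "others"), 300, replace = TRUE)
  yp <- ifelse(runif(300) < 0.8, yt, sample(c("polyp", "normal", "others"),
                                            300, replace = TRUE))
  cm <- confusion_matrix(yt, yp, c("polyp", "normal", "others"))
  tab <- class_metrics(cm)
  expect_identical(tab$class, c("polyp", "normal", "others", "Average"))
  expect_equal(tab$recall[4], mean(tab$recall[1:3]))
  # label-order invariance of the per-class rows
  cm2 <- confusion_matrix(yt, yp, c("others", "polyp", "normal"))
  tab2 <- class_metrics(cm2)
  expect_equal(tab2$recall[tab2$class == "polyp"],
               tab$recall[tab$class == "polyp"])
})

test_that("report writers emit the per-class + Average layout", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         c("A", "B"))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  iipnet:::write_metrics_report(cm, csv, js)
  tab <- utils::read.csv(csv)
  expect_identical(tab$class, c("A", "B", "Average"))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$overall_accuracy,
               iipnet:::round_half_up(overall_accuracy(cm)))
})
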