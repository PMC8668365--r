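# One-vs-rest evaluation suite: confusion matrix (rows = predicted class,
# columns = actual class), per-class precision/recall/specificity/F1, macro
# averages and overall accuracy.  All internal math is full precision;
# rounding (half-up, 2 decimals) happens only at presentation.

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion matrix with the predicted-row convention
#'
#' `counts[p, a]` is the number of samples predicted as class `p` whose
#' actual class is `a`.
#'
#' @param y_true,y_pred label sequences of equal length.
#' @param labels ordered class labels; must cover every observed value.
#' @return an object of class `iipnet_cm`: an integer `k x k` matrix with
#'   dimnames `predicted` x `actual`.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  labels <- as.character(labels)
  unseen <- setdiff(unique(c(as.character(y_true), as.character(y_pred))), labels)
  if (length(unseen)) {
    stop(sprintf("label(s) not in `labels`: %s", paste(unseen, collapse = ", ")),
         call. = FALSE)
  }
  m <- table(factor(y_pred, levels = labels), factor(y_true, levels = labels))
  cm <- matrix(as.integer(m), length(labels), length(labels),
               dimnames = list(predicted = labels, actual = labels))
  structure(cm, class = c("iipnet_cm", "matrix"))
}

new_cm <- function(counts, labels = rownames(counts)) {
  if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  structure(matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = list(predicted = labels, actual = labels)),
            class = c("iipnet_cm", "matrix"))
}

#' One-vs-rest reduction of a confusion matrix
#'
#' The chosen class is positive, every other class is negative:
#' `TP = counts[c, c]`, `FP` = rest of predicted row `c`, `FN` = rest of
#' actual column `c`, `TN` = everything else.  The four counts always sum
#' to the matrix total.
#'
#' @param cm a confusion matrix (predicted rows x actual columns).
#' @param class the positive class label.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest <- function(cm, class) {
  labels <- rownames(cm)
  class <- as.character(class)
  if (!class %in% labels) {
    stop(sprintf("unknown class \"%s\"", class), call. = FALSE)
  }
  tp <- cm[class, class]
  fp <- sum(cm[class, ]) - tp
  fn <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Per-class metric row from one-vs-rest counts
#'
#' Computes precision, recall, specificity and F1 (as percentages), plus
#' the per-class accuracy column of the family's report tables, which
#' equals precision under the tables' convention.  Cells with a zero
#' denominator are reported as `NA` (undefined), never as 0 or 100.
#'
#' @param TP,FP,FN,TN non-negative one-vs-rest counts.
#' @return a one-row tibble with columns `precision`, `recall`,
#'   `specificity`, `f1`, `class_accuracy`, all in `[0, 100]`.
#' @export
metric_row <- function(TP, FP, FN, TN) {
  TP <- unname(TP)
  FP <- unname(FP)
  FN <- unname(FN)
  TN <- unname(TN)
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, TN + FP)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else {
    NA_real_
  }
  tibble::tibble(
    precision = 100 * .env$precision, recall = 100 * .env$recall,
    specificity = 100 * .env$specificity, f1 = 100 * .env$f1,
    class_accuracy = 100 * .env$precision
  )
}

#' Unweighted macro average of per-class metric rows
#'
#' The "Average" row of the report tables: the plain arithmetic mean of
#' each metric over classes, ignoring class support.
#'
#' @param rows a tibble of per-class metric rows (numeric columns averaged;
#'   a `class` column, if present, becomes `"Average"`).
#' @export
macro_average <- function(rows) {
  if (nrow(rows) < 1) stop("macro_average needs at least one row", call. = FALSE)
  num <- vapply(rows, is.numeric, logical(1))
  out <- tibble::as_tibble(lapply(rows[num], mean))
  if ("class" %in% names(rows)) out <- tibble::add_column(out, class = "Average", .before = 1)
  out
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total, as a percentage.  Algebraically identical to the
#' support-weighted mean of the per-class recalls.
#'
#' @param cm a confusion matrix.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Per-class metric table with macro-average row
#'
#' The full report table: one row per class (accuracy, precision, recall,
#' specificity, F1) plus the unweighted `Average` row.
#'
#' @param cm a confusion matrix from [confusion_matrix()].
#' @return a tibble with a `class` column and metric columns in percent.
#' @export
class_metrics <- function(cm) {
  labels <- rownames(cm)
  rows <- dplyr::bind_rows(lapply(labels, function(cl) {
    counts <- one_vs_rest(cm, cl)
    tibble::add_column(
      metric_row(counts["TP"], counts["FP"], counts["FN"], counts["TN"]),
      class = cl, .before = 1)
  }))
  dplyr::bind_rows(rows, macro_average(rows))
}

#' @export
print.iipnet_cm <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = actual)\n")
  print(unclass(x))
  cat(sprintf("overall accuracy: %.2f%%\n", round_half_up(overall_accuracy(x))))
  invisible(x)
}

#' @export
tidy.iipnet_cm <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x), responseName = "n"))
}

#' Confusion-matrix heat map
#'
#' @param object an `iipnet_cm`.
#' @param ... unused.
#' @export
autoplot.iipnet_cm <- function(object, ...) {
  df <- tidy.iipnet_cm(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "actual class", y = "predicted class", fill = "count")
}

# CSV/JSON report writers with the per-class + Average layout.
write_metrics_report <- function(cm, path_csv = NULL, path_json = NULL) {
  tab <- class_metrics(cm)
  pres <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                           ~ round_half_up(.x, 2)))
  if (!is.null(path_csv)) utils::write.csv(pres, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      overall_accuracy = round_half_up(overall_accuracy(cm), 2),
      per_class = pres,
      confusion_matrix = unclass(cm)
    ), path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(tab)
}
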