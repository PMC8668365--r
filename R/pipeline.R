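# Training and evaluation pipeline: preprocessing, data loading, the SGD
# training loop with per-epoch test accuracy and best-checkpoint tracking,
# and Table-style evaluation reports.

#' Training configuration
#'
#' Defaults follow the family's published protocol: batch size 32, learning
#' rate 0.001, weight decay 5e-4, momentum 0.9, 100 epochs (the 4-class
#' protocol uses batch size 16 and 200 epochs; pass them explicitly).
#'
#' @param batch_size minibatch size.
#' @param learning_rate SGD learning rate (constant; no schedule).
#' @param weight_decay L2 weight decay coefficient.
#' @param momentum classical momentum coefficient.
#' @param epochs number of training epochs (0 is allowed: no optimizer
#'   step, evaluation of the initial weights only).
#' @param seed seed controlling initialisation and data order.
#' @param depth,head,num_classes,input_size model spec fields, see
#'   [model_spec()].
#' @param augment apply seeded augmentation on the fly to training images
#'   (in addition to any offline [expand_dataset()] expansion recorded in
#'   the manifest).
#' @param device informational tag; this implementation is CPU-only.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 0.001,
                         weight_decay = 5e-4, momentum = 0.9, epochs = 100,
                         seed = 1, depth = 54, head = "GAP-FC",
                         num_classes = 3, input_size = 256, augment = FALSE,
                         device = "cpu") {
  stopifnot(batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            momentum >= 0, momentum < 1, epochs >= 0)
  cfg <- list(batch_size = as.integer(batch_size),
              learning_rate = learning_rate, weight_decay = weight_decay,
              momentum = momentum, epochs = as.integer(epochs),
              seed = as.integer(seed), depth = as.integer(depth),
              head = toupper(head), num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              augment = isTRUE(augment), device = device)
  model_spec(cfg$depth, cfg$head, cfg$num_classes, cfg$input_size)  # validates
  structure(cfg, class = "train_config")
}

#' Read / write a training configuration as YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, path))` is
#' field-identical to `cfg`.
#'
#' @param config a [train_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: \"%s\"", path), call. = FALSE)
  }
  do.call(train_config, yaml::read_yaml(path))
}

#' Read an RGB image file
#'
#' @param path PNG file path.
#' @return an `[H, W, 3]` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Preprocess one image
#'
#' Detects and crops a near-white frame (border rows/columns whose mean
#' intensity exceeds `white_threshold`), resizes to `size x size`
#' (bilinear), rescales to `[0, 1]`, and optionally standardizes per
#' channel.
#'
#' @param image an `[H, W, 3]` array in `[0, 255]`.
#' @param size output side in pixels.
#' @param mean,sd optional per-channel standardization constants (length
#'   3, on the `[0, 1]` scale); both or neither.
#' @param white_threshold border intensity above which a row/column counts
#'   as white frame (default 240 of 255).
#' @return a `size x size x 3` array, `[0, 1]` or standardized.
#' @export
preprocess_image <- function(image, size = 256, mean = NULL, sd = NULL,
                             white_threshold = 240) {
  d <- dim(image)
  row_mean <- rowMeans(matrix(image, d[1]))
  col_mean <- apply(image, 2, mean)
  top <- 1
  while (top < d[1] && row_mean[top] > white_threshold) top <- top + 1
  bottom <- d[1]
  while (bottom > top && row_mean[bottom] > white_threshold) bottom <- bottom - 1
  left <- 1
  while (left < d[2] && col_mean[left] > white_threshold) left <- left + 1
  right <- d[2]
  while (right > left && col_mean[right] > white_threshold) right <- right - 1
  if (row_mean[top] > white_threshold) {
    stop("image is entirely white: no content to crop to", call. = FALSE)
  }
  cropped <- image[top:bottom, left:right, , drop = FALSE]
  out <- resize_bilinear(cropped, size, size) / 255
  if (!is.null(mean)) {
    for (ch in 1:3) out[, , ch] <- (out[, , ch] - mean[ch]) / sd[ch]
  }
  out
}

# Canonical label order used for model outputs and report tables.
dataset_labels <- function(manifest) {
  intersect(iipnet_labels, unique(manifest$label))
}

# Load one split as a preprocessed [S, S, 3, N] batch in [0, 1] (before
# standardization), applying manifest augmentation seeds on the fly.
load_split <- function(manifest, split, size, data_dir = attr(manifest, "out_dir"),
                       augment_extra = FALSE) {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop(sprintf("split \"%s\" is empty", split), call. = FALSE)
  labels <- dataset_labels(manifest)
  x <- array(0, c(size, size, 3, nrow(rows)))
  for (i in seq_len(nrow(rows))) {
    img <- read_image(file.path(data_dir, rows$path[i]))
    if (!is.na(rows$aug_seed[i])) img <- augment(img, rows$aug_seed[i])
    x[, , , i] <- preprocess_image(img, size)
  }
  list(x = x, y = as.integer(factor(rows$label, levels = labels)),
       labels = labels)
}

standardize_batch <- function(x, mean, sd) {
  for (ch in 1:3) x[, , ch, ] <- (x[, , ch, ] - mean[ch]) / sd[ch]
  x
}

#' Train an IIP-Net on a manifest dataset
#'
#' Optimizes softmax cross-entropy with SGD (momentum + L2 weight decay)
#' at a constant learning rate.  Per-channel standardization constants are
#' computed on the training split and applied to both splits.  After every
#' epoch the test split is evaluated and the weights with the best test
#' accuracy are retained for the final report.  The run is deterministic
#' given `config$seed`.
#'
#' @param config a [train_config()].
#' @param manifest a dataset manifest from [make_dataset()] /
#'   [expand_dataset()] / [read_manifest()].
#' @param data_dir dataset root directory (defaults to the manifest's).
#' @param verbose print one line per epoch.
#' @return an object of class `iipnet_run`: config, per-epoch history,
#'   the best model, its evaluation report and the standardization
#'   constants.
#' @export
train_model <- function(config, manifest, data_dir = attr(manifest, "out_dir"),
                        verbose = interactive()) {
  labels <- dataset_labels(manifest)
  if (length(labels) != config$num_classes) {
    stop(sprintf("manifest has %d classes (%s) but config expects %d",
                 length(labels), paste(labels, collapse = ", "),
                 config$num_classes), call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  tr <- load_split(manifest, "train", config$input_size, data_dir)
  te <- load_split(manifest, "test", config$input_size, data_dir)
  ch_mean <- vapply(1:3, function(ch) mean(tr$x[, , ch, ]), numeric(1))
  ch_sd <- vapply(1:3, function(ch) stats::sd(tr$x[, , ch, ]), numeric(1))
  ch_sd[ch_sd < 1e-8] <- 1
  tr$x <- standardize_batch(tr$x, ch_mean, ch_sd)
  te$x <- standardize_batch(te$x, ch_mean, ch_sd)

  model <- build_model(model_spec(config$depth, config$head,
                                  config$num_classes, config$input_size))
  params <- model_param_nodes(model)
  n_train <- dim(tr$x)[4]

  eval_accuracy <- function() {
    probs <- predict(model, te$x, batch_size = config$batch_size)
    100 * mean(max.col(probs, ties.method = "first") == te$y)
  }

  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            test_accuracy = numeric())
  best <- list(acc = -Inf, state = model_state(model), epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_train)
    loss_sum <- 0
    for (start in seq(1, n_train, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n_train)]
      xb <- tr$x[, , , idx, drop = FALSE]
      if (config$augment) {
        for (j in seq_along(idx)) {
          aug_seed <- derive_seed(config$seed + epoch, idx[j])
          xb[, , , j] <- augment(xb[, , , j] * 255, aug_seed) / 255
        }
      }
      fw <- model_forward(model, xb, training = TRUE)
      loss <- op_softmax_crossentropy(fw$tape, fw$logits, tr$y[idx])
      loss_value <- loss$value  # read before backward releases the tape
      ag_zero_grads(params)
      ag_backward(fw$tape, loss)
      sgd_step(params, config$learning_rate, config$momentum,
               config$weight_decay)
      loss_sum <- loss_sum + loss_value * length(idx)
      fw <- NULL
      loss <- NULL
    }
    gc(FALSE)  # cap the allocation churn of the step loop
    acc <- eval_accuracy()
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, loss = loss_sum / n_train, test_accuracy = acc))
    if (acc > best$acc) {
      best <- list(acc = acc, state = model_state(model), epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  test accuracy %.2f%%",
                      epoch, loss_sum / n_train, acc))
    }
  }
  restore_model_state(model, best$state)
  attr(model, "meta") <- list(labels = labels,
                              norm = list(mean = ch_mean, sd = ch_sd))
  report <- evaluate_batch(model, te$x, te$y, labels)
  structure(
    list(config = config, history = history, best_epoch = best$epoch,
         model = model, report = report,
         norm = list(mean = ch_mean, sd = ch_sd),
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "iipnet_run"
  )
}

evaluate_batch <- function(model, x, y, labels) {
  probs <- predict(model, x)
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(labels[y], labels[pred], labels)
  structure(
    list(confusion = cm, table = class_metrics(cm),
         overall_accuracy = overall_accuracy(cm)),
    class = "iipnet_eval"
  )
}

#' Evaluate a model or checkpoint on a manifest split
#'
#' Runs the network in evaluation mode over the split, builds the
#' confusion matrix and the per-class + Average metric table, and reports
#' overall accuracy.
#'
#' @param model an `iipnet_model` (with standardization metadata) or the
#'   path of a checkpoint saved by [save_checkpoint()].
#' @param manifest dataset manifest.
#' @param data_dir dataset root.
#' @param split `"test"` or `"train"`.
#' @return an object of class `iipnet_eval`.
#' @export
evaluate_model <- function(model, manifest,
                           data_dir = attr(manifest, "out_dir"),
                           split = "test") {
  if (is.character(model)) model <- load_checkpoint(model)
  meta <- attr(model, "meta")
  da <- load_split(manifest, split, model$spec$input_size, data_dir)
  if (length(da$labels) != model$spec$num_classes) {
    stop(sprintf("manifest has %d classes but the checkpoint expects %d",
                 length(da$labels), model$spec$num_classes), call. = FALSE)
  }
  if (!is.null(meta$norm)) {
    da$x <- standardize_batch(da$x, meta$norm$mean, meta$norm$sd)
  }
  evaluate_batch(model, da$x, da$y, da$labels)
}

#' @export
print.iipnet_eval <- function(x, ...) {
  pres <- dplyr::mutate(x$table,
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ round_half_up(.x, 2)))
  print(pres, n = Inf)
  cat(sprintf("overall accuracy: %.2f%%\n", round_half_up(x$overall_accuracy)))
  invisible(x)
}

#' @export
tidy.iipnet_eval <- function(x, ...) x$table

#' @export
glance.iipnet_eval <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 n = sum(x$confusion), classes = nrow(x$confusion))
}

#' @export
autoplot.iipnet_eval <- function(object, ...) autoplot.iipnet_cm(object$confusion)

#' @export
print.iipnet_run <- function(x, ...) {
  cat(sprintf("<IIP-Net%d-%s run: %d epochs, best test accuracy %.2f%% (epoch %d)>\n",
              x$config$depth, x$config$head, x$config$epochs,
              if (nrow(x$history)) max(x$history$test_accuracy) else NA,
              x$best_epoch))
  invisible(x)
}

#' @export
tidy.iipnet_run <- function(x, ...) x$history

#' @export
glance.iipnet_run <- function(x, ...) {
  tibble::tibble(
    epochs = x$config$epochs, best_epoch = x$best_epoch,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    best_test_accuracy = if (nrow(x$history)) max(x$history$test_accuracy) else NA_real_,
    overall_accuracy = x$report$overall_accuracy,
    wall_time = x$wall_time
  )
}

#' Training-curve plot for a run
#'
#' @param object an `iipnet_run`.
#' @param ... unused.
#' @export
autoplot.iipnet_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
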