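#' Describe one IIP-Net variant
#'
#' An IIP-Net is identified by its depth (the number of weight-bearing
#' layers), its classifier head and the number of classes.  The backbone is
#' a stem (7x7/64 stride-2 convolution + 3x3 stride-2 max-pool) followed by
#' four residual bottleneck stages with a CIIP attention block after each of
#' stages 1-3; the attention vector of each CIIP block feeds the next.
#'
#' @param depth one of 54, 105, 156.  The stage block multipliers are
#'   (2,3,5,3), (2,3,22,3) and (2,7,35,3) respectively, and
#'   [count_weight_layers()] of the built model equals the depth exactly.
#' @param head classifier head: `"FC"` (single linear layer on the flattened
#'   map), `"GAP-FC"` (global average pooling then a linear layer) or
#'   `"C-GAP"` (1x1 convolution then global average pooling).  All heads end
#'   in softmax.
#' @param num_classes number of output classes (3 or 4 in the intended use).
#' @param input_size input image side in pixels; must be a multiple of 32.
#' @return an object of class `iipnet_spec`.
#' @export
model_spec <- function(depth = 54, head = "GAP-FC", num_classes = 3,
                       input_size = 256) {
  blocks <- switch(as.character(depth),
    "54" = c(2L, 3L, 5L, 3L),
    "105" = c(2L, 3L, 22L, 3L),
    "156" = c(2L, 7L, 35L, 3L),
    stop("depth must be one of 54, 105, 156", call. = FALSE)
  )
  head <- toupper(head)
  if (!head %in% c("FC", "GAP-FC", "C-GAP")) {
    stop("head must be one of \"FC\", \"GAP-FC\", \"C-GAP\"", call. = FALSE)
  }
  stopifnot(num_classes >= 2, input_size >= 32, input_size %% 32 == 0)
  structure(
    list(depth = as.integer(depth), head = head,
         num_classes = as.integer(num_classes),
         input_size = as.integer(input_size),
         stage_blocks = blocks, ciip_channels = c(256L, 512L, 1024L)),
    class = "iipnet_spec"
  )
}

#' @export
print.iipnet_spec <- function(x, ...) {
  cat(sprintf("<IIP-Net%d-%s spec: %d classes, %dx%d input, stage blocks %s>\n",
              x$depth, x$head, x$num_classes, x$input_size, x$input_size,
              paste(x$stage_blocks, collapse = "/")))
  invisible(x)
}

spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

spec_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  model_spec(x$depth, x$head, x$num_classes, x$input_size)
}

# ---- model builder -------------------------------------------------------

# The builder keeps a registry of parameter nodes, batch-norm state
# environments and layer descriptors.  Descriptors power the complexity
# module: each carries its parameter count, its multiply-add closed form as
# a function of the input image side, and whether it counts towards the
# depth-naming convention (stem + 3 per bottleneck + 3/5/5 for the CIIP
# blocks + 1 head layer; projection shortcuts and normalizations do not).
new_registry <- function() {
  r <- new.env(parent = emptyenv())
  r$params <- list()
  r$bn <- list()
  r$layers <- list()
  r
}

reg_param <- function(reg, name, node) {
  node$name <- name
  reg$params[[name]] <- node
  node
}

reg_layer <- function(reg, name, type, group, nparams, counted = FALSE,
                      flops = function(S) 0) {
  reg$layers[[length(reg$layers) + 1L]] <-
    list(name = name, type = type, group = group, nparams = nparams,
         counted = counted, flops = flops)
}

# "Conv" composite of the backbone: convolution + batch norm (+ ReLU).
make_conv_bn <- function(reg, name, group, kh, kw, cin, cout, stride, pad,
                         div_out, counted) {
  w <- reg_param(reg, paste0(name, ".w"), new_conv_param(kh, kw, cin, cout, name))
  gamma <- reg_param(reg, paste0(name, ".bn.gamma"), ag_param(rep(1, cout)))
  beta <- reg_param(reg, paste0(name, ".bn.beta"), ag_param(rep(0, cout)))
  state <- new.env(parent = emptyenv())
  reg$bn[[paste0(name, ".bn")]] <- state
  reg_layer(reg, name, "conv", group, length(w$value), counted,
            flops = function(S) kh * kw * cin * cout * (S / div_out)^2)
  reg_layer(reg, paste0(name, ".bn"), "batchnorm", group, 2 * cout)
  function(tape, x, training, relu = TRUE) {
    h <- op_conv(tape, x, w, stride = stride, pad = pad)
    h <- op_batchnorm(tape, h, gamma, beta, state, training)
    if (relu) h <- op_relu(tape, h) else h
  }
}

# Residual bottleneck block (1x1 reduce, 3x3, 1x1 restore; ReLU after the
# residual addition).  Downsampling stride sits on the 3x3 convolution;
# the projection shortcut (1x1, matching stride) exists only where shape
# changes, and is not a counted weight layer.
make_bottleneck_block <- function(reg, name, group, cin, width, cout, stride,
                                  div_in) {
  div_out <- div_in * stride
  c1 <- make_conv_bn(reg, paste0(name, ".conv1"), group, 1, 1, cin, width,
                     1, 0, div_in, counted = TRUE)
  c2 <- make_conv_bn(reg, paste0(name, ".conv2"), group, 3, 3, width, width,
                     stride, 1, div_out, counted = TRUE)
  c3 <- make_conv_bn(reg, paste0(name, ".conv3"), group, 1, 1, width, cout,
                     1, 0, div_out, counted = TRUE)
  proj <- NULL
  if (stride != 1 || cin != cout) {
    proj <- make_conv_bn(reg, paste0(name, ".proj"), group, 1, 1, cin, cout,
                         stride, 0, div_out, counted = FALSE)
  }
  function(tape, x, training) {
    h <- c1(tape, x, training)
    h <- c2(tape, h, training)
    h <- c3(tape, h, training, relu = FALSE)
    sc <- if (is.null(proj)) x else proj(tape, x, training, relu = FALSE)
    op_relu(tape, op_add(tape, sc, h))
  }
}

# CIIP module wrapper: registers the block's parameters/descriptors and
# returns a forward closure.  First-branch blocks count 3 weight layers
# (the bottleneck convolutions); follow-up blocks count 5 (those plus the
# channel-matching FC and the attention convolution).
make_ciip_module <- function(reg, name, group, channels, prev_channels, div) {
  pr <- ciip_params(channels, prev_channels)
  p <- pr$params
  cr <- channels %/% pr$reduction
  reg_param(reg, paste0(name, ".w_reduce"), p$w_reduce)
  reg_param(reg, paste0(name, ".ln1.gamma"), p$ln1$gamma)
  reg_param(reg, paste0(name, ".ln1.beta"), p$ln1$beta)
  reg_param(reg, paste0(name, ".w_mid"), p$w_mid)
  reg_param(reg, paste0(name, ".ln2.gamma"), p$ln2$gamma)
  reg_param(reg, paste0(name, ".ln2.beta"), p$ln2$beta)
  reg_param(reg, paste0(name, ".w_restore"), p$w_restore)
  reg_param(reg, paste0(name, ".ln3.gamma"), p$ln3$gamma)
  reg_param(reg, paste0(name, ".ln3.beta"), p$ln3$beta)
  reg_layer(reg, paste0(name, ".w_reduce"), "conv", group, channels * cr,
            counted = TRUE, flops = function(S) channels * cr * (S / div)^2)
  reg_layer(reg, paste0(name, ".ln1"), "layernorm", group, 2 * cr)
  reg_layer(reg, paste0(name, ".w_mid"), "conv", group, 9 * cr * cr,
            counted = TRUE, flops = function(S) 9 * cr * cr * (S / div)^2)
  reg_layer(reg, paste0(name, ".ln2"), "layernorm", group, 2 * cr)
  reg_layer(reg, paste0(name, ".w_restore"), "conv", group, cr * channels,
            counted = TRUE, flops = function(S) cr * channels * (S / div)^2)
  reg_layer(reg, paste0(name, ".ln3"), "layernorm", group, 2 * channels)
  if (!is.null(prev_channels)) {
    reg_param(reg, paste0(name, ".fc_w"), p$fc_w)
    reg_param(reg, paste0(name, ".fc_ln.gamma"), p$fc_ln$gamma)
    reg_param(reg, paste0(name, ".fc_ln.beta"), p$fc_ln$beta)
    reg_param(reg, paste0(name, ".att_w"), p$att_w)
    reg_param(reg, paste0(name, ".att_ln.gamma"), p$att_ln$gamma)
    reg_param(reg, paste0(name, ".att_ln.beta"), p$att_ln$beta)
    reg_layer(reg, paste0(name, ".fc_match"), "linear", group,
              channels * prev_channels, counted = TRUE,
              flops = function(S) channels * prev_channels)
    reg_layer(reg, paste0(name, ".fc_ln"), "layernorm", group, 2 * channels)
    reg_layer(reg, paste0(name, ".att_conv"), "linear", group,
              channels * channels, counted = TRUE,
              flops = function(S) channels * channels)
    reg_layer(reg, paste0(name, ".att_ln"), "layernorm", group, 2 * channels)
  }
  function(tape, x, att_prev, training) ciip_fwd(tape, x, att_prev, pr)
}

make_head <- function(reg, spec) {
  k <- spec$num_classes
  D <- 2048L
  hw <- spec$input_size %/% 32L
  if (spec$head == "FC") {
    w <- reg_param(reg, "head.fc.w",
                   ag_param(kaiming_uniform(c(k, hw * hw * D), hw * hw * D)))
    b <- reg_param(reg, "head.fc.b", ag_param(rep(0, k)))
    reg_layer(reg, "head.fc", "linear", "head", length(w$value) + k,
              counted = TRUE, flops = function(S) (S / 32)^2 * D * k)
    function(tape, x, training) op_linear(tape, op_flatten(tape, x), w, b)
  } else if (spec$head == "GAP-FC") {
    s <- reg_param(reg, "head.pool_scale", ag_param(rep(1, D)))
    w <- reg_param(reg, "head.fc.w", ag_param(kaiming_uniform(c(k, D), D)))
    b <- reg_param(reg, "head.fc.b", ag_param(rep(0, k)))
    reg_layer(reg, "head.pool_scale", "scale", "head", D)
    reg_layer(reg, "head.fc", "linear", "head", D * k + k,
              counted = TRUE, flops = function(S) D * k)
    function(tape, x, training) {
      op_linear(tape, op_scale_vec(tape, op_gap(tape, x), s), w, b)
    }
  } else {  # C-GAP
    w <- reg_param(reg, "head.conv.w", new_conv_param(1, 1, D, k, "head.conv"))
    b <- reg_param(reg, "head.conv.b", ag_param(rep(0, k)))
    pb <- reg_param(reg, "head.posbias", ag_param(array(0, c(hw, hw, k))))
    reg_layer(reg, "head.conv", "conv", "head", D * k + k,
              counted = TRUE, flops = function(S) D * k * (S / 32)^2)
    reg_layer(reg, "head.posbias", "posbias", "head", hw * hw * k)
    function(tape, x, training) {
      h <- op_bias_channel(tape, op_conv(tape, x, w), b)
      op_gap(tape, op_posbias(tape, h, pb))
    }
  }
}

#' Build an IIP-Net model
#'
#' Assembles the full network described by a [model_spec()]: stem, four
#' bottleneck stages (stride-2 downsampling on the 3x3 convolution of the
#' first block of stages 2-4), a CIIP block after each of stages 1-3 with
#' the attention vector chained forward, and the requested classifier head.
#' Weights are He-uniform initialised from the current RNG stream, so
#' [set.seed()] makes construction reproducible.
#'
#' @param spec a [model_spec()].
#' @return an object of class `iipnet_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "iipnet_spec"))
  reg <- new_registry()
  widths <- c(64L, 128L, 256L, 512L)
  couts <- c(256L, 512L, 1024L, 2048L)
  divs <- c(4L, 8L, 16L, 32L)  # output spatial divisor per stage

  stem <- make_conv_bn(reg, "stem.conv", "stem", 7, 7, 3, 64, 2, 3, 2,
                       counted = TRUE)
  reg_layer(reg, "stem.pool", "pool", "stem", 0)

  stages <- vector("list", 4)
  cin <- 64L
  for (s in 1:4) {
    blocks <- vector("list", spec$stage_blocks[s])
    for (b in seq_len(spec$stage_blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      din <- if (b == 1) divs[s] / stride else divs[s]
      blocks[[b]] <- make_bottleneck_block(
        reg, sprintf("stage%d.block%d", s, b), sprintf("stage%d", s),
        cin, widths[s], couts[s], stride, din)
      cin <- couts[s]
    }
    stages[[s]] <- blocks
  }

  ciips <- list(
    make_ciip_module(reg, "ciip1", "ciip1", 256L, NULL, 4L),
    make_ciip_module(reg, "ciip2", "ciip2", 512L, 256L, 8L),
    make_ciip_module(reg, "ciip3", "ciip3", 1024L, 512L, 16L)
  )
  head <- make_head(reg, spec)

  model <- structure(
    list(spec = spec, reg = reg, stem = stem, stages = stages,
         ciips = ciips, head = head),
    class = "iipnet_model"
  )
  model
}

#' @export
print.iipnet_model <- function(x, ...) {
  cat(sprintf("<IIP-Net%d-%s: %d classes, %s parameters, %d weight layers>\n",
              x$spec$depth, x$spec$head, x$spec$num_classes,
              format(sum(vapply(x$reg$params, function(p) length(p$value), 0)),
                     big.mark = ","),
              count_weight_layers(x)))
  invisible(x)
}

# Forward pass to the logits node; returns list(tape, logits).
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != 3) {
    stop(sprintf("input batch must be [H, W, 3, N]; got channels = %s",
                 if (length(d) >= 3) d[3] else "?"), call. = FALSE)
  }
  if (d[1] < 32 || d[2] < 32) stop("input side must be at least 32", call. = FALSE)
  tape <- ag_tape()
  h <- model$stem(tape, ag_const(x), training)
  h <- op_maxpool(tape, h)
  att <- NULL
  for (s in 1:4) {
    for (blk in model$stages[[s]]) h <- blk(tape, h, training)
    if (s < 4) {
      res <- model$ciips[[s]](tape, h, att, training)
      h <- res$output
      att <- res$att
    }
  }
  list(tape = tape, logits = model$head(tape, h, training))
}

#' Class probabilities for a batch of images
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' returns softmax class probabilities.
#'
#' @param object an `iipnet_model`.
#' @param x an `[H, W, 3]` image or `[H, W, 3, N]` batch (standardized
#'   intensities, as produced by [preprocess_image()]).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return an `N x k` matrix of probabilities; rows sum to 1.
#' @export
predict.iipnet_model <- function(object, x, batch_size = 32L, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, object$spec$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- model_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- t(softmax_cols(fw$logits$value))
  }
  out
}

#' Number of weight-bearing layers of a model
#'
#' Counts convolutional and fully connected layers under the depth-naming
#' convention of the family: the stem convolution, three convolutions per
#' bottleneck block, three layers for the first CIIP block and five for
#' each follow-up CIIP block (bottleneck convolutions + channel-matching FC
#' + attention convolution), and one classifier layer.  Projection
#' shortcuts and normalization layers are not counted.  For every valid
#' spec the result equals `spec$depth`.
#'
#' @param model an `iipnet_model`.
#' @return integer layer count.
#' @export
count_weight_layers <- function(model) {
  sum(vapply(model$reg$layers, function(l) isTRUE(l$counted), logical(1)))
}

model_param_nodes <- function(model) model$reg$params

# ---- checkpointing -------------------------------------------------------

model_state <- function(model) {
  list(
    values = lapply(model$reg$params, function(p) p$value),
    bn = lapply(model$reg$bn, function(s) list(mean = s$mean, var = s$var))
  )
}

restore_model_state <- function(model, state) {
  for (nm in names(state$values)) model$reg$params[[nm]]$value <- state$values[[nm]]
  for (nm in names(state$bn)) {
    model$reg$bn[[nm]]$mean <- state$bn[[nm]]$mean
    model$reg$bn[[nm]]$var <- state$bn[[nm]]$var
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the named weight arrays,
#' batch-norm running statistics, the model spec (as JSON) and optional
#' metadata such as the per-channel standardization constants.
#'
#' @param model an `iipnet_model`.
#' @param path file path.
#' @param meta optional named list stored alongside the weights.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  saveRDS(list(spec_json = as.character(spec_to_json(model$spec)),
               state = model_state(model), meta = meta),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(spec_from_json(ck$spec_json))
  restore_model_state(model, ck$state)
  attr(model, "meta") <- ck$meta
  model
}
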