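#' Closed-form classifier-head parameter counts
#'
#' For a last convolutional feature map of size `H x W x D` and `k` classes,
#' the three classifier heads have these exact parameter counts:
#' \itemize{
#'   \item FC: `H*W*D*k + k` — one linear layer on the flattened map.
#'   \item GAP-FC: `D + D*k + k` — a per-channel scale on the pooled
#'     descriptor plus one linear layer.
#'   \item C-GAP: `H*W*k + D*k + k` — a 1x1 convolution (weights + bias)
#'     plus a per-position bias grid on the k-channel map before pooling.
#' }
#' With `k = 3` these recover the printed forms `HxWxDx3+3`, `D+Dx3+3` and
#' `HxWx3+Dx3+3`.
#'
#' @param kind `"FC"`, `"GAP-FC"` or `"C-GAP"`.
#' @param H,W,D feature-map height, width and channel count; all `>= 1`.
#' @param k number of classes.
#' @return integer parameter count.
#' @export
head_params <- function(kind, H, W, D, k) {
  stopifnot(H >= 1, W >= 1, D >= 1, k >= 1)
  switch(toupper(kind),
    "FC" = H * W * D * k + k,
    "GAP-FC" = D + D * k + k,
    "C-GAP" = H * W * k + D * k + k,
    stop(sprintf("unknown head kind \"%s\" (use FC, GAP-FC or C-GAP)", kind),
         call. = FALSE)
  )
}

#' Exhaustive parameter count of a model
#'
#' Sums every learnable scalar (convolution and linear weights, biases,
#' normalization affine parameters, head scale/bias grids; batch-norm
#' running statistics are not learnable and are excluded) and returns a
#' per-component breakdown.  The head total always equals the
#' [head_params()] closed form for the model's actual feature dimensions.
#'
#' @param model an `iipnet_model` from [build_model()].
#' @return a `complexity_report` (see [complexity_report()]) without
#'   multiply-add counts.
#' @export
count_params <- function(model) {
  complexity_report(model, flops = FALSE)
}

#' Forward-pass multiply-add count
#'
#' Counts one multiply-add per convolution or linear-layer
#' multiply-accumulate (`kh*kw*Cin*Cout*Hout*Wout` per convolution,
#' `in*out` per linear layer); pooling, normalization and activations are
#' free under this convention.
#'
#' @param model an `iipnet_model`.
#' @param input_size input image side in pixels (multiple of 32); defaults
#'   to the spec's.
#' @return total multiply-adds for one forward pass of one image.
#' @export
count_flops <- function(model, input_size = model$spec$input_size) {
  if (input_size %% 32 != 0) {
    stop("input_size must be a multiple of 32", call. = FALSE)
  }
  sum(vapply(model$reg$layers, function(l) l$flops(input_size), numeric(1)))
}

#' Complexity report for a model
#'
#' Per-component parameter and multiply-add accounting, with model totals
#' and the classifier-head closed form as a cross-check.
#'
#' @inheritParams count_flops
#' @param flops also compute multiply-add counts.
#' @return an object of class `complexity_report`: a list with
#'   `total_params`, `head_params`, `multiply_adds` (NA when `flops =
#'   FALSE`) and a `breakdown` tibble (component, params, multiply_adds).
#' @export
complexity_report <- function(model, input_size = model$spec$input_size,
                              flops = TRUE) {
  layers <- model$reg$layers
  groups <- vapply(layers, `[[`, character(1), "group")
  nparams <- vapply(layers, `[[`, numeric(1), "nparams")
  macs <- if (flops) {
    vapply(layers, function(l) l$flops(input_size), numeric(1))
  } else {
    rep(NA_real_, length(layers))
  }
  ord <- unique(groups)
  breakdown <- tibble::tibble(
    component = ord,
    params = unname(vapply(ord, function(g) sum(nparams[groups == g]),
                           numeric(1))),
    multiply_adds = unname(vapply(ord, function(g) sum(macs[groups == g]),
                                  numeric(1)))
  )
  hw <- model$spec$input_size %/% 32L
  structure(
    list(
      spec = model$spec,
      input_size = input_size,
      total_params = sum(nparams),
      head_params = sum(nparams[groups == "head"]),
      head_params_formula = head_params(model$spec$head, hw, hw, 2048L,
                                        model$spec$num_classes),
      multiply_adds = if (flops) sum(macs) else NA_real_,
      breakdown = breakdown
    ),
    class = "complexity_report"
  )
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("IIP-Net%d-%s complexity at %dx%d input\n",
              x$spec$depth, x$spec$head, x$input_size, x$input_size))
  cat(sprintf("  parameters:    %s (head: %s)\n",
              format(x$total_params, big.mark = ","),
              format(x$head_params, big.mark = ",")))
  if (!is.na(x$multiply_adds)) {
    cat(sprintf("  multiply-adds: %s\n", format(x$multiply_adds, big.mark = ",")))
  }
  print(x$breakdown, n = Inf)
  invisible(x)
}

#' @export
tidy.complexity_report <- function(x, ...) x$breakdown

#' @export
glance.complexity_report <- function(x, ...) {
  tibble::tibble(
    depth = x$spec$depth, head = x$spec$head, classes = x$spec$num_classes,
    input_size = x$input_size, total_params = x$total_params,
    head_params = x$head_params, multiply_adds = x$multiply_adds
  )
}

complexity_to_json <- function(x) {
  jsonlite::toJSON(list(
    depth = x$spec$depth, head = x$spec$head, classes = x$spec$num_classes,
    input_size = x$input_size, total_params = x$total_params,
    head_params = x$head_params, multiply_adds = x$multiply_adds,
    breakdown = x$breakdown
  ), auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
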