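# Minimal reverse-mode automatic differentiation over R arrays.
#
# A forward pass builds a tape: every operation appends a node holding its
# value, its parent nodes and a vector-Jacobian-product closure.  Backward
# walks the tape in reverse creation order (a valid reverse topological
# order) and accumulates gradients into nodes, including off-tape leaves
# (parameters and inputs).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ag_node <- function(value, parents = list(), vjp = NULL, tape = NULL,
                    param = FALSE, name = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$vjp <- vjp
  n$param <- param
  n$name <- name
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- n
  }
  n
}

# A trainable leaf: carries its value, accumulated gradient and optimizer
# state (momentum buffer) across steps.
ag_param <- function(value, name = NULL) {
  n <- ag_node(value, param = TRUE, name = name)
  n$state <- new.env(parent = emptyenv())
  n
}

ag_const <- function(value) ag_node(value)

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the tape.  Intermediate
# gradients and activations are released as soon as they have been
# consumed, which keeps the peak heap close to the forward-pass footprint.
ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$vjp)) {
      gs <- n$vjp(n$grad)
      for (j in seq_along(n$parents)) {
        p <- n$parents[[j]]
        g <- gs[[j]]
        if (is.null(g) || is.null(p)) next
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    if (!n$param) {
      n$grad <- NULL
      n$value <- NULL  # closures hold whatever backward still needs
      n$vjp <- NULL
    }
    tape$nodes[i] <- list(NULL)
  }
  tape$n <- 0L
  invisible(NULL)
}

# One SGD step with classical momentum and L2 weight decay:
#   v <- mu * v + (g + wd * w);  w <- w - lr * v
sgd_step <- function(params, lr, momentum = 0, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    v <- p$state$velocity
    v <- if (is.null(v)) g else momentum * v + g
    p$state$velocity <- v
    p$value <- p$value - lr * v
  }
  invisible(NULL)
}
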