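#' Reverse-mode automatic differentiation core
#'
#' A compact tape-based autodiff engine backing the segmentation network
#' and its losses.  Values are wrapped in `agt` nodes (environments holding
#' the value, parents, and a backward closure); arithmetic on `agt` nodes
#' builds the tape, and [agt_backward()] accumulates gradients in reverse
#' topological order.  The loss functions in this package are written
#' against plain arrays and dispatch transparently to these nodes, so the
#' same code is used for evaluation and for training.  Convolutions are
#' delegated to compiled im2col kernels.
#'
#' @name autodiff
#' @keywords internal
NULL

.agt_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

agt_node <- function(value, parents = list(), bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bwd <- bwd
  e$grad <- NULL
  e$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires, logical(1)))
  e$nid <- .agt_counter()
  class(e) <- "agt"
  e
}

#' Wrap a constant value for the tape
#' @keywords internal
agt_const <- function(value) agt_node(value)

#' Create a trainable parameter node
#' @keywords internal
agt_param <- function(value) {
  e <- agt_node(value)
  e$requires <- TRUE
  e$is_param <- TRUE
  e
}

agt_value <- function(x) if (inherits(x, "agt")) x$value else x

is_agt <- function(x) inherits(x, "agt")

# reduce a gradient to the shape of the operand (scalar broadcast only)
reduce_grad <- function(g, ref) {
  if (length(ref) == 1L) sum(g) else g
}

#' @export
Ops.agt <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) {
    if (op == "-") return(e1 * -1)
    if (op == "+") return(e1)
    stop("unsupported unary op for agt: ", op)
  }
  v1 <- agt_value(e1); v2 <- agt_value(e2)
  if (op %in% c("==", "!=", "<", ">", "<=", ">="))
    return(get(op)(v1, v2))
  parents <- Filter(is_agt, list(e1, e2))
  val <- get(op)(v1, v2)
  bwd <- switch(op,
    "+" = function(g) {
      out <- list()
      if (is_agt(e1)) out <- c(out, list(reduce_grad(g, v1)))
      if (is_agt(e2)) out <- c(out, list(reduce_grad(g, v2)))
      out
    },
    "-" = function(g) {
      out <- list()
      if (is_agt(e1)) out <- c(out, list(reduce_grad(g, v1)))
      if (is_agt(e2)) out <- c(out, list(reduce_grad(-g, v2)))
      out
    },
    "*" = function(g) {
      out <- list()
      if (is_agt(e1)) out <- c(out, list(reduce_grad(g * v2, v1)))
      if (is_agt(e2)) out <- c(out, list(reduce_grad(g * v1, v2)))
      out
    },
    "/" = function(g) {
      out <- list()
      if (is_agt(e1)) out <- c(out, list(reduce_grad(g / v2, v1)))
      if (is_agt(e2)) out <- c(out, list(reduce_grad(-g * v1 / v2^2, v2)))
      out
    },
    "^" = {
      if (is_agt(e2)) stop("agt exponents are not supported")
      function(g) list(reduce_grad(g * v2 * v1^(v2 - 1), v1))
    },
    stop("unsupported op for agt: ", op)
  )
  if (op %in% c("==", "!=", "<", ">", "<=", ">="))
    return(get(op)(v1, v2))
  agt_node(val, parents, bwd)
}

#' @export
Math.agt <- function(x, ...) {
  v <- x$value
  switch(.Generic,
    log = agt_node(log(v), list(x), function(g) list(g / v)),
    exp = {
      out <- exp(v)
      agt_node(out, list(x), function(g) list(g * out))
    },
    sqrt = {
      out <- sqrt(v)
      agt_node(out, list(x), function(g) list(g / (2 * out)))
    },
    stop("unsupported math op for agt: ", .Generic)
  )
}

#' Sum / mean that respect the tape
#' @keywords internal
tsum <- function(x) UseMethod("tsum")
#' @export
tsum.default <- function(x) sum(x)
#' @export
tsum.agt <- function(x) {
  v <- x$value
  agt_node(sum(v), list(x), function(g) list(array(g, dim(v) %||% length(v))))
}

#' @keywords internal
tmean <- function(x) UseMethod("tmean")
#' @export
tmean.default <- function(x) mean(x)
#' @export
tmean.agt <- function(x) {
  v <- x$value
  n <- length(v)
  agt_node(mean(v), list(x),
           function(g) list(array(g / n, dim(v) %||% n)))
}

#' Clamp with pass-through gradient inside the bounds
#' @keywords internal
tclamp <- function(x, lo, hi) UseMethod("tclamp")
#' @export
tclamp.default <- function(x, lo, hi) clamp(x, lo, hi)
#' @export
tclamp.agt <- function(x, lo, hi) {
  v <- x$value
  inside <- (v >= lo & v <= hi) * 1
  agt_node(clamp(v, lo, hi), list(x), function(g) list(g * inside))
}

# subset with gradient (drop = FALSE semantics via logical/integer index)
agt_index <- function(x, idx) {
  if (!is_agt(x)) return(x[idx])
  v <- x$value
  agt_node(v[idx], list(x), function(g) {
    out <- array(0, dim(v) %||% length(v))
    out[idx] <- g
    list(out)
  })
}

agt_matmul <- function(a, b) {
  va <- agt_value(a); vb <- agt_value(b)
  parents <- Filter(is_agt, list(a, b))
  if (length(parents) == 0L) return(va %*% vb)
  agt_node(va %*% vb, parents, function(g) {
    out <- list()
    if (is_agt(a)) out <- c(out, list(g %*% t(vb)))
    if (is_agt(b)) out <- c(out, list(t(va) %*% g))
    out
  })
}

agt_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  vx <- agt_value(x); vw <- agt_value(w); vb <- agt_value(b)
  y <- conv2d_fwd(vx, vw, vb, stride, pad)
  parents <- Filter(is_agt, list(x, w, b))
  need_gx <- is_agt(x) && x$requires
  agt_node(y, parents, function(g) {
    gr <- conv2d_bwd(vx, vw, g, stride, pad, need_gx)
    out <- list()
    if (is_agt(x)) out <- c(out, list(gr$gx))
    if (is_agt(w)) out <- c(out, list(gr$gw))
    if (is_agt(b)) out <- c(out, list(gr$gb))
    out
  })
}

agt_leaky_relu <- function(x, slope = 0.01) {
  v <- agt_value(x)
  out <- lrelu_fwd(v, slope)
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) list(lrelu_bwd(v, g, slope)))
}

agt_sigmoid <- function(x) {
  v <- agt_value(x)
  s <- 1 / (1 + exp(-v))
  if (!is_agt(x)) return(s)
  agt_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# nearest-neighbour x2 upsampling of (H, W, C, N)
agt_upsample2 <- function(x) {
  v <- agt_value(x)
  d <- dim(v)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  out <- v[ri, ci, , , drop = FALSE]
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    gg <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    gg[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
      gg[, seq(2, 2 * d[2], 2), , , drop = FALSE] -> gx
    list(gx)
  })
}

# 2x2 stride-2 average pooling (dims must be even)
agt_avgpool2 <- function(x) {
  v <- agt_value(x)
  d <- dim(v)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  e1 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  out <- (v[o1, e1, , , drop = FALSE] + v[o2, e1, , , drop = FALSE] +
            v[o1, e2, , , drop = FALSE] + v[o2, e2, , , drop = FALSE]) / 4
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    gx <- array(0, d)
    gx[o1, e1, , ] <- g / 4
    gx[o2, e1, , ] <- g / 4
    gx[o1, e2, , ] <- g / 4
    gx[o2, e2, , ] <- g / 4
    list(gx)
  })
}

# zero-pad (bottom/right) to (h_out, w_out)
agt_pad_to <- function(x, h_out, w_out) {
  v <- agt_value(x)
  d <- dim(v)
  if (d[1] == h_out && d[2] == w_out) return(x)
  out <- array(0, c(h_out, w_out, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- v
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g)
    list(g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]))
}

# crop to the top-left (h_out, w_out)
agt_crop_to <- function(x, h_out, w_out) {
  v <- agt_value(x)
  d <- dim(v)
  if (d[1] == h_out && d[2] == w_out) return(x)
  out <- v[seq_len(h_out), seq_len(w_out), , , drop = FALSE]
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    gx <- array(0, d)
    gx[seq_len(h_out), seq_len(w_out), , ] <- g
    list(gx)
  })
}

# global average pool (H, W, C, N) -> (C, N)
agt_gap <- function(x) {
  v <- agt_value(x)
  d <- dim(v)
  out <- apply(v, c(3, 4), mean)
  dim(out) <- c(d[3], d[4])
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    gx <- array(rep(as.vector(g), each = d[1] * d[2]) / (d[1] * d[2]), d)
    list(gx)
  })
}

# L2-normalize the columns of a (D, N) matrix
agt_l2norm_cols <- function(x, eps = 1e-12) {
  v <- agt_value(x)
  nrm <- sqrt(colSums(v^2) + eps)
  out <- sweep(v, 2, nrm, "/")
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    dot <- colSums(g * v)
    gx <- sweep(g, 2, nrm, "/") -
      sweep(v, 2, dot / nrm^3, "*")
    list(gx)
  })
}

#' Run backward accumulation from a scalar loss node
#' @keywords internal
agt_backward <- function(root) {
  stopifnot(is_agt(root), length(root$value) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$nid)
    if (top$stage == 0L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 1L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$nid)]]) && p$requires)
          stack[[length(stack) + 1L]] <- list(node = p, stage = 0L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  for (node in order) node$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$bwd)) next
    grads <- node$bwd(node$grad)
    gi <- 1L
    for (p in node$parents) {
      if (!is_agt(p)) next
      if (p$requires) {
        g <- grads[[gi]]
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
      gi <- gi + 1L
    }
  }
  invisible(root)
}
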