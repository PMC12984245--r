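#' Neural-network layers and optimizer
#'
#' Minimal layer set used by the segmentation network: 2D convolution,
#' batch normalization (with running statistics), linear layers, and an
#' AdamW optimizer with per-group learning rates and cosine decay.
#'
#' @name layers
#' @keywords internal
NULL

he_init <- function(fan_in, dims) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

layer_conv2d <- function(cin, cout, k = 3L, stride = 1L,
                         pad = as.integer(k %/% 2)) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv2d"
  e$stride <- as.integer(stride)
  e$pad <- as.integer(pad)
  e$w <- agt_param(he_init(k * k * cin, c(k, k, cin, cout)))
  e$b <- agt_param(numeric(cout))
  e$b$no_decay <- TRUE
  class(e) <- "cf_layer"
  e
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$momentum <- momentum
  e$eps <- eps
  e$gamma <- agt_param(rep(1, c))
  e$beta <- agt_param(numeric(c))
  e$gamma$no_decay <- TRUE
  e$beta$no_decay <- TRUE
  e$running_mean <- numeric(c)
  e$running_var <- rep(1, c)
  class(e) <- "cf_layer"
  e
}

layer_linear <- function(din, dout) {
  e <- new.env(parent = emptyenv())
  e$type <- "linear"
  e$w <- agt_param(matrix(rnorm(dout * din, 0, sqrt(2 / din)), dout, din))
  e$b <- agt_param(numeric(dout))
  e$b$no_decay <- TRUE
  class(e) <- "cf_layer"
  e
}

conv_forward <- function(layer, x) {
  agt_conv2d(x, layer$w, layer$b, layer$stride, layer$pad)
}

bn_forward <- function(layer, x, training = TRUE) {
  v <- agt_value(x)
  d <- dim(v)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_dot(v, NULL) / m
    var <- pmax(channel_dot(v, v) / m - mu^2, 0)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * var
  } else {
    mu <- layer$running_mean
    var <- layer$running_var
  }
  istd <- 1 / sqrt(var + layer$eps)
  gam <- layer$gamma$value
  y <- bn_scale_shift(v, gam * istd, layer$beta$value - gam * istd * mu)
  agt_node(y, Filter(is_agt, list(x, layer$gamma, layer$beta)),
           function(g) {
    xhat <- bn_scale_shift(v, istd, -mu * istd)
    dbeta <- channel_dot(g, NULL)
    dgamma <- channel_dot(g, xhat)
    out <- list()
    if (is_agt(x)) {
      a <- gam * istd
      if (training) {
        dx <- bn_scale_shift(g, a, -a * dbeta / m) -
          bn_scale_shift(xhat, a * dgamma / m, numeric(d[3]))
      } else {
        dx <- bn_scale_shift(g, a, numeric(d[3]))
      }
      out <- c(out, list(dx))
    }
    c(out, list(dgamma, dbeta))
  })
}

linear_forward <- function(layer, x) {
  vx <- agt_value(x)
  w <- layer$w
  b <- layer$b
  y <- w$value %*% vx + b$value
  agt_node(y, Filter(is_agt, list(x, w, b)), function(g) {
    out <- list()
    if (is_agt(x)) out <- c(out, list(t(w$value) %*% g))
    c(out, list(g %*% t(vx), rowSums(g)))
  })
}

layer_params <- function(layer) {
  switch(layer$type,
         conv2d = list(layer$w, layer$b),
         linear = list(layer$w, layer$b),
         bn = list(layer$gamma, layer$beta))
}

collect_params <- function(x) {
  if (inherits(x, "cf_layer")) return(layer_params(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' AdamW update over parameter groups
#'
#' @param groups list of `list(params = <list of agt params>, lr = <rate>)`.
#' @param betas,eps,weight_decay AdamW hyperparameters.
#' @keywords internal
adamw_step <- function(groups, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 0.01) {
  for (g in groups) {
    for (p in g$params) {
      if (is.null(p$grad)) next
      if (is.null(p$opt_m)) {
        p$opt_m <- p$value * 0
        p$opt_v <- p$value * 0
        p$opt_t <- 0L
      }
      p$opt_t <- p$opt_t + 1L
      p$opt_m <- betas[1] * p$opt_m + (1 - betas[1]) * p$grad
      p$opt_v <- betas[2] * p$opt_v + (1 - betas[2]) * p$grad^2
      mhat <- p$opt_m / (1 - betas[1]^p$opt_t)
      vhat <- p$opt_v / (1 - betas[2]^p$opt_t)
      wd <- if (isTRUE(p$no_decay)) 0 else weight_decay
      p$value <- p$value - g$lr * (mhat / (sqrt(vhat) + eps) +
                                     wd * p$value)
    }
  }
  invisible(NULL)
}

cosine_lr <- function(epoch, n_epochs, lr_start = 1e-4, lr_end = 1e-5) {
  t <- if (n_epochs <= 1L) 1 else (epoch - 1) / (n_epochs - 1)
  lr_end + (lr_start - lr_end) * (1 + cos(pi * t)) / 2
}
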