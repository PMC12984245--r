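#' Probability-map fusion
#'
#' Combines the cortex and vessel probability masks with the four-class
#' output of any per-pixel HS tissue classifier into a refined four-class
#' map.  The classifier's probabilities `(Ph, Pt, Pv, Pd)` are first
#' reduced to a healthy / non-healthy pair
#' `Qclf = softmax([Ph, max(Pt, Pv, Pd)])`; the fused output is
#' `Pout = [Qclf * (1 - Pvsl) * Pctx, Pvsl * Pctx, 1 - Pctx]` with slots
#' (healthy, tumor, vessel, background) -- the vessel probability is
#' preserved wherever the cortex mask is active, anything outside the
#' cortex becomes background, and dura is folded into non-healthy and
#' never reappears.  The per-pixel probabilities sum to one by algebra.
#'
#' @name fusion
NULL

#' Reduce four-class tissue probabilities to healthy vs non-healthy
#'
#' Per pixel, `softmax([Ph, max(Pt, Pv, Pd)])` applied to the
#' probabilities as given.
#'
#' @param pclf array `(h, w, 4)` of (healthy, tumor, vessel, dura)
#'   probabilities summing to 1 per pixel.
#' @return array `(h, w, 2)` summing to 1 per pixel.
#' @export
transform_probs <- function(pclf) {
  if (any(!is.finite(pclf))) stop("tissue probabilities contain NaN/Inf")
  d <- dim(pclf)
  stopifnot(length(d) == 3L, d[3] == 4L)
  m <- pmax(pclf[, , 2], pclf[, , 3], pclf[, , 4])
  e1 <- exp(pclf[, , 1]); e2 <- exp(m)
  out <- array(0, c(d[1], d[2], 2L))
  out[, , 1] <- e1 / (e1 + e2)
  out[, , 2] <- e2 / (e1 + e2)
  out
}

#' Fuse cortex/vessel masks with the reduced tissue probabilities
#'
#' @param qclf array `(h, w, 2)` from [transform_probs()].
#' @param pctx,pvsl cortex and vessel probability maps `(h, w)`.
#' @return a `fused_map`: list with `probs` `(h, w, 4)` over (healthy,
#'   tumor, vessel, background) and the argmax `class_map` (ties toward
#'   the lower class index).
#' @export
fuse <- function(qclf, pctx, pvsl) {
  d <- dim(qclf)
  if (!all(dim(pctx) == d[1:2]) || !all(dim(pvsl) == d[1:2]))
    stop("map shapes differ")
  if (max(abs(qclf[, , 1] + qclf[, , 2] - 1)) > 1e-6)
    stop("qclf must sum to 1 per pixel")
  probs <- array(0, c(d[1], d[2], 4L))
  probs[, , 1] <- qclf[, , 1] * (1 - pvsl) * pctx
  probs[, , 2] <- qclf[, , 2] * (1 - pvsl) * pctx
  probs[, , 3] <- pvsl * pctx
  probs[, , 4] <- 1 - pctx
  flat <- matrix(probs, ncol = 4L)
  class_map <- matrix(max.col(flat, ties.method = "first"), d[1], d[2])
  structure(list(probs = probs, class_map = class_map),
            class = "fused_map")
}

#' Render a fused map as an RGB image
#'
#' Healthy green, tumor red, vessels blue, background gray.
#'
#' @param fused a `fused_map`.
#' @return array `(h, w, 3)` in `[0, 1]`.
#' @export
render_map <- function(fused) {
  palette <- rbind(healthy = c(0.00, 0.70, 0.15),
                   tumor = c(0.85, 0.05, 0.05),
                   vessel = c(0.10, 0.15, 0.85),
                   background = c(0.55, 0.55, 0.55))
  cm <- fused$class_map
  out <- array(0, c(nrow(cm), ncol(cm), 3L))
  for (k in 1:3) out[, , k] <- matrix(palette[cm, k], nrow(cm), ncol(cm))
  out
}

# softmax cross-entropy on logits (C, N) with integer labels, custom node
softmax_ce <- function(logits, labels) {
  v <- agt_value(logits)
  mx <- apply(v, 2, max)
  e <- exp(sweep(v, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(v)
  picked <- p[cbind(labels, seq_len(n))]
  val <- -mean(log(pmax(picked, 1e-12)))
  if (!is_agt(logits)) return(val)
  agt_node(val, list(logits), function(g) {
    onehot <- matrix(0, nrow(v), n)
    onehot[cbind(labels, seq_len(n))] <- 1
    list(g * (p - onehot) / n)
  })
}

#' Train the reference per-pixel tissue classifier
#'
#' A small fully connected network over single HS pixels (two hidden
#' layers of 28 and 40 neurons, softmax over the 4 tissue classes),
#' trained with AdamW under cosine learning-rate decay with
#' accuracy-based model selection every 10 epochs.  The default schedule
#' is sized for desk-scale batches.  It provides the four-class
#' probabilities the fusion stage refines.
#'
#' @param pixels matrix `(n, bands)` of normalized HS pixels.
#' @param labels integer class labels 1-4 (healthy, tumor, vessel, dura);
#'   all four classes must be present.
#' @param epochs,batch,lr_start,lr_end,val_every,seed training settings.
#' @return a `tissue_classifier`.
#' @export
train_reference_classifier <- function(pixels, labels, epochs = 800L,
                                       batch = 512L, lr_start = 3e-3,
                                       lr_end = 3e-4, val_every = 10L,
                                       seed = 0L) {
  pixels <- as.matrix(pixels)
  if (length(unique(labels)) < 4L)
    stop("all four tissue classes must be present in the training labels")
  nb <- ncol(pixels)
  withr::with_seed(seed, {
    net <- list(fc1 = layer_linear(nb, 28L), fc2 = layer_linear(28L, 40L),
                fc3 = layer_linear(40L, 4L))
    params <- collect_params(net)
    fwd <- function(x) {
      h1 <- agt_leaky_relu(linear_forward(net$fc1, x), 0.01)
      h2 <- agt_leaky_relu(linear_forward(net$fc2, h1), 0.01)
      linear_forward(net$fc3, h2)
    }
    n <- nrow(pixels)
    best <- list(acc = -Inf, state = lapply(params, function(p) p$value))
    for (ep in seq_len(epochs)) {
      lr <- cosine_lr(ep, epochs, lr_start, lr_end)
      idx <- sample.int(n, min(batch, n))
      x <- t(pixels[idx, , drop = FALSE])
      loss <- softmax_ce(fwd(x), labels[idx])
      zero_grads(params)
      agt_backward(loss)
      adamw_step(list(list(params = params, lr = lr)))
      if (ep %% val_every == 0L || ep == epochs) {
        logits <- agt_value(fwd(t(pixels)))
        acc <- mean(max.col(t(logits)) == labels)
        if (acc > best$acc)
          best <- list(acc = acc,
                       state = lapply(params, function(p) p$value))
      }
    }
    for (i in seq_along(params)) params[[i]]$value <- best$state[[i]]
    structure(list(net = net, n_bands = nb, accuracy = best$acc),
              class = "tissue_classifier")
  })
}

#' Four-class probabilities of a classifier over a cube
#'
#' @param clf a `tissue_classifier`.
#' @param cube_norm array `(h, w, bands)` of normalized HS data, or an
#'   [hsi_cube()] (band-major data is rearranged automatically).
#' @return array `(h, w, 4)` of softmax probabilities.
#' @export
classify_cube <- function(clf, cube_norm) {
  if (inherits(cube_norm, "hsi_cube"))
    cube_norm <- aperm(cube_norm$data, c(2, 3, 1))
  d <- dim(cube_norm)
  x <- t(matrix(cube_norm, ncol = d[3]))
  net <- clf$net
  h1 <- agt_leaky_relu(linear_forward(net$fc1, agt_value(x)), 0.01)
  h2 <- agt_leaky_relu(linear_forward(net$fc2, agt_value(h1)), 0.01)
  logits <- agt_value(linear_forward(net$fc3, agt_value(h2)))
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  array(t(p), c(d[1], d[2], 4L))
}
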