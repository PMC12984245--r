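#' Dual-modality cortex/vessel segmentation network
#'
#' An encoder-decoder ResNet that segments the exposed brain surface and
#' its cortical vessels, producing two sigmoid probability maps at the
#' input resolution.  RGB images enter through a ResNet-C style stem; HSI
#' cubes first pass through a spectral stem of three valid 3x3
#' convolutions (25 -> 16 -> 8 -> 3 channels, with batch norm and leaky
#' ReLU) that reduces them to three channels feedable to the shared RGB
#' trunk -- the trunk weights are common to both modalities.  The encoder
#' stacks 14 residual blocks (ResNet-B) in three stages with ResNet-D
#' downsampling between stages; the decoder upsamples by nearest-neighbour
#' x2, adds linearly projected encoder skips, and applies two 3x3
#' conv+BN+leaky-ReLU blocks per stage.  A projection head (two linear
#' layers, embedding width 256) over the pooled encoder output serves the
#' contrastive pre-training and is discarded afterwards.
#'
#' @name cortexnet
NULL

#' Network configuration
#'
#' @param base_channels trunk width at full resolution.
#' @param stage_blocks residual blocks per encoder stage; the default
#'   `c(4, 4, 6)` totals 14.
#' @param embedding_dim projection-head width.
#' @param hsi_in_bands spectral bands of the HSI input.
#' @param leaky_slope negative slope of the leaky ReLU activations.
#' @export
network_config <- function(base_channels = 8L, stage_blocks = c(4L, 4L, 6L),
                           embedding_dim = 256L, hsi_in_bands = 25L,
                           leaky_slope = 0.01) {
  stopifnot(length(stage_blocks) == 3L, all(stage_blocks >= 1L),
            base_channels >= 1L, embedding_dim >= 8L)
  list(base_channels = as.integer(base_channels),
       stage_blocks = as.integer(stage_blocks),
       embedding_dim = as.integer(embedding_dim),
       hsi_in_bands = as.integer(hsi_in_bands),
       leaky_slope = leaky_slope)
}

res_block <- function(c) {
  list(conv1 = layer_conv2d(c, c, 3L), bn1 = layer_bn(c),
       conv2 = layer_conv2d(c, c, 3L), bn2 = layer_bn(c))
}

down_block <- function(cin, cout) {
  list(conv1 = layer_conv2d(cin, cout, 3L, stride = 2L), bn1 = layer_bn(cout),
       conv2 = layer_conv2d(cout, cout, 3L), bn2 = layer_bn(cout),
       proj = layer_conv2d(cin, cout, 1L, pad = 0L), bnp = layer_bn(cout))
}

dec_block <- function(cin, cskip, cout) {
  list(skip_proj = if (!is.null(cskip))
         layer_conv2d(cskip, cin, 1L, pad = 0L),
       conv1 = layer_conv2d(cin, cout, 3L), bn1 = layer_bn(cout),
       conv2 = layer_conv2d(cout, cout, 3L), bn2 = layer_bn(cout))
}

#' Build the segmentation network
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return a `cortexnet` model object.
#' @export
build_cortexnet <- function(config = network_config(), seed = 0L) {
  withr::with_seed(seed, {
    bc <- config$base_channels
    model <- list(
      config = config,
      hsi_stem = list(
        conv1 = layer_conv2d(config$hsi_in_bands, 16L, 3L, pad = 0L),
        bn1 = layer_bn(16L),
        conv2 = layer_conv2d(16L, 8L, 3L, pad = 0L), bn2 = layer_bn(8L),
        conv3 = layer_conv2d(8L, 3L, 3L, pad = 0L), bn3 = layer_bn(3L)),
      rgb_stem = list(
        conv1 = layer_conv2d(3L, bc, 3L, stride = 2L), bn1 = layer_bn(bc),
        conv2 = layer_conv2d(bc, bc, 3L), bn2 = layer_bn(bc),
        conv3 = layer_conv2d(bc, bc, 3L), bn3 = layer_bn(bc)),
      encoder = list(
        stage1 = lapply(seq_len(config$stage_blocks[1]),
                        function(i) res_block(bc)),
        down2 = down_block(bc, 2L * bc),
        stage2 = lapply(seq_len(config$stage_blocks[2]),
                        function(i) res_block(2L * bc)),
        down3 = down_block(2L * bc, 4L * bc),
        stage3 = lapply(seq_len(config$stage_blocks[3]),
                        function(i) res_block(4L * bc))),
      decoder = list(
        dec1 = dec_block(4L * bc, 2L * bc, 2L * bc),
        dec2 = dec_block(2L * bc, bc, bc),
        dec3 = dec_block(bc, NULL, bc)),
      head = list(
        conv1 = layer_conv2d(bc, bc, 1L, pad = 0L), bn1 = layer_bn(bc),
        conv2 = layer_conv2d(bc, 2L, 1L, pad = 0L)),
      projection = list(
        fc1 = layer_linear(4L * bc, config$embedding_dim),
        fc2 = layer_linear(config$embedding_dim, config$embedding_dim))
    )
    class(model) <- "cortexnet"
    model
  })
}

cbl <- function(conv, bn, x, training, slope) {
  agt_leaky_relu(bn_forward(bn, conv_forward(conv, x), training), slope)
}

res_forward <- function(block, x, training, slope) {
  y <- cbl(block$conv1, block$bn1, x, training, slope)
  y <- bn_forward(block$bn2, conv_forward(block$conv2, y), training)
  agt_leaky_relu(y + x, slope)
}

down_forward <- function(block, x, training, slope) {
  d <- dim(agt_value(x))
  he <- d[1] + d[1] %% 2L
  we <- d[2] + d[2] %% 2L
  x <- agt_pad_to(x, he, we)
  y <- cbl(block$conv1, block$bn1, x, training, slope)
  y <- bn_forward(block$bn2, conv_forward(block$conv2, y), training)
  s <- bn_forward(block$bnp, conv_forward(block$proj, agt_avgpool2(x)),
                  training)
  agt_leaky_relu(y + s, slope)
}

dec_forward <- function(block, x, skip, dims, training, slope) {
  y <- agt_crop_to(agt_upsample2(x), dims[1], dims[2])
  if (!is.null(skip) && !is.null(block$skip_proj))
    y <- y + conv_forward(block$skip_proj, skip)
  y <- cbl(block$conv1, block$bn1, y, training, slope)
  cbl(block$conv2, block$bn2, y, training, slope)
}

# reflect-pad the spatial dims of (H, W, C, N) by p on every side
reflect_pad <- function(x, p) {
  d <- dim(x)
  ri <- c((p + 1L):2L, seq_len(d[1]), (d[1] - 1L):(d[1] - p))
  ci <- c((p + 1L):2L, seq_len(d[2]), (d[2] - 1L):(d[2] - p))
  x[ri, ci, , , drop = FALSE]
}

hsi_stem_apply <- function(model, x, training) {
  slope <- model$config$leaky_slope
  st <- model$hsi_stem
  # 3 valid convolutions eat a 3-pixel margin; reflect-pad to preserve dims
  x <- reflect_pad(x, 3L)
  y <- cbl(st$conv1, st$bn1, x, training, slope)
  y <- cbl(st$conv2, st$bn2, y, training, slope)
  cbl(st$conv3, st$bn3, y, training, slope)
}

#' Spectral stem: reduce a 25-band image to a 3-channel feature image
#'
#' @param model a `cortexnet`.
#' @param cube_batch array `(h, w, bands, n)` of normalized HSI data.
#' @param training batch-norm mode.
#' @return array `(h, w, 3, n)`.
#' @export
hsi_stem_forward <- function(model, cube_batch, training = FALSE) {
  if (dim(cube_batch)[3] != model$config$hsi_in_bands)
    stop("wrong spectral band count for the HSI stem")
  agt_value(hsi_stem_apply(model, cube_batch, training))
}

# full forward pass; returns agt nodes for the tape
net_forward <- function(model, x, modality = c("rgb", "hsi"),
                        training = TRUE) {
  modality <- match.arg(modality)
  slope <- model$config$leaky_slope
  d_in <- dim(agt_value(x))[1:2]
  if (modality == "hsi") {
    if (dim(agt_value(x))[3] != model$config$hsi_in_bands)
      stop("hsi input must have the configured band count")
    x <- hsi_stem_apply(model, x, training)
  } else if (dim(agt_value(x))[3] != 3L) {
    stop("rgb input must have 3 channels")
  }
  st <- model$rgb_stem
  y <- cbl(st$conv1, st$bn1, x, training, slope)
  y <- cbl(st$conv2, st$bn2, y, training, slope)
  stem_out <- cbl(st$conv3, st$bn3, y, training, slope)
  s1 <- stem_out
  for (b in model$encoder$stage1) s1 <- res_forward(b, s1, training, slope)
  s2 <- down_forward(model$encoder$down2, s1, training, slope)
  for (b in model$encoder$stage2) s2 <- res_forward(b, s2, training, slope)
  s3 <- down_forward(model$encoder$down3, s2, training, slope)
  for (b in model$encoder$stage3) s3 <- res_forward(b, s3, training, slope)

  d1 <- dim(agt_value(s2))[1:2]
  d2 <- dim(agt_value(s1))[1:2]
  y <- dec_forward(model$decoder$dec1, s3, s2, d1, training, slope)
  y <- dec_forward(model$decoder$dec2, y, s1, d2, training, slope)
  y <- dec_forward(model$decoder$dec3, y, NULL, d_in, training, slope)
  hd <- model$head
  y <- cbl(hd$conv1, hd$bn1, y, training, slope)
  logits <- conv_forward(hd$conv2, y)
  list(probs = agt_sigmoid(logits), encoder_out = s3)
}

agt_channel <- function(x, ch) {
  v <- agt_value(x)
  out <- v[, , ch, , drop = FALSE]
  dim(out) <- dim(v)[c(1, 2, 4)]
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g) {
    gx <- array(0, dim(v))
    gx[, , ch, ] <- g
    list(gx)
  })
}

#' Segment a batch of images
#'
#' @param model a `cortexnet`.
#' @param x array `(h, w, c, n)`; `c` is 3 for RGB, the configured band
#'   count for HSI.
#' @param modality `"rgb"` or `"hsi"`.
#' @param training batch-norm mode (`FALSE` for inference).
#' @return list with `cortex_prob` and `vessel_prob`, arrays `(h, w, n)`
#'   of probabilities in `(0, 1)` at the input resolution.
#' @export
predict_masks <- function(model, x, modality = c("rgb", "hsi"),
                          training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  out <- net_forward(model, x, modality, training)
  probs <- agt_value(out$probs)
  list(cortex_prob = array(probs[, , 1L, ], dim(probs)[c(1, 2, 4)]),
       vessel_prob = array(probs[, , 2L, ], dim(probs)[c(1, 2, 4)]))
}

#' Contrastive projection embeddings of image patches
#'
#' Global-average-pools the encoder output, L2-normalizes, applies the
#' two-layer projection head, and L2-normalizes again.
#'
#' @param model a `cortexnet`.
#' @param x array `(h, w, c, n)`.
#' @param modality input modality.
#' @param training batch-norm mode.
#' @return for plain evaluation, a matrix `(embedding_dim, n)` of
#'   unit-norm columns (an `agt` node during training).
#' @export
project_embedding <- function(model, x, modality = "rgb",
                              training = FALSE, as_value = TRUE) {
  out <- net_forward(model, x, modality, training)
  pooled <- agt_l2norm_cols(agt_gap(out$encoder_out))
  h <- agt_leaky_relu(linear_forward(model$projection$fc1, pooled),
                      model$config$leaky_slope)
  z <- agt_l2norm_cols(linear_forward(model$projection$fc2, h))
  if (as_value) agt_value(z) else z
}

#' Extract / load model weights
#'
#' Checkpoints are nested named lists of plain arrays grouped as
#' `hsi_stem`, `rgb_stem`, `encoder`, `decoder`, `head`, `projection`, so
#' partial loading (e.g. the trunk only) is explicit.
#'
#' @param model a `cortexnet`.
#' @return nested list of weights.
#' @export
model_state <- function(model) {
  grab <- function(x) {
    if (inherits(x, "cf_layer")) {
      st <- lapply(layer_params(x), function(p) p$value)
      names(st) <- c(if (x$type == "bn") c("gamma", "beta")
                     else c("w", "b"))
      if (x$type == "bn") {
        st$running_mean <- x$running_mean
        st$running_var <- x$running_var
      }
      return(st)
    }
    if (is.list(x)) return(lapply(x, grab))
    NULL
  }
  parts <- c("hsi_stem", "rgb_stem", "encoder", "decoder", "head",
             "projection")
  st <- lapply(parts, function(p) grab(model[[p]]))
  names(st) <- parts
  st$config <- model$config
  st
}

#' @rdname model_state
#' @param state a checkpoint from [model_state()].
#' @param parts which weight groups to load (default: all present).
#' @export
load_state <- function(model, state,
                       parts = c("hsi_stem", "rgb_stem", "encoder",
                                 "decoder", "head", "projection")) {
  put <- function(layer, st) {
    if (inherits(layer, "cf_layer")) {
      if (layer$type == "bn") {
        layer$gamma$value <- st$gamma
        layer$beta$value <- st$beta
        layer$running_mean <- st$running_mean
        layer$running_var <- st$running_var
      } else {
        layer$w$value <- st$w
        layer$b$value <- st$b
      }
      return(invisible(NULL))
    }
    if (is.list(layer))
      for (k in seq_along(layer))   # stages are unnamed block lists
        if (!is.null(layer[[k]]) && k <= length(st) && !is.null(st[[k]]))
          put(layer[[k]], st[[k]])
    invisible(NULL)
  }
  for (p in intersect(parts, names(state))) put(model[[p]], state[[p]])
  invisible(model)
}

model_params <- function(model,
                         parts = c("hsi_stem", "rgb_stem", "encoder",
                                   "decoder", "head", "projection")) {
  do.call(c, lapply(parts, function(p) collect_params(model[[p]])))
}
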