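#' Training objectives
#'
#' The compound losses used across the three training steps: DSC+BCE
#' segmentation terms, the contour loss, the self- and cross-hull shape
#' priors, the excess loss penalizing vessel activation outside the
#' refined annotation, the supervised contrastive loss for encoder
#' pre-training, the masked BCE terms for HSI fine-tuning against the
#' adjusted ground truth, and the equivariance regularizer.  All losses
#' are pure functions of plain arrays; during training the same code runs
#' on tape nodes, with the non-differentiable geometry (concave hulls,
#' Canny edges) computed on detached binarized predictions and treated as
#' constant targets within the step.
#'
#' @name losses
NULL

P_EPS <- 1e-6

#' Loss configuration
#'
#' @param alpha excess-loss scale factor (default 10).
#' @param tau supervised-contrastive temperature (default 0.1).
#' @param binarize_threshold threshold for hull/contour geometry.
#' @export
loss_config <- function(alpha = 10, tau = 0.1, binarize_threshold = 0.5) {
  stopifnot(alpha > 0, tau > 0,
            binarize_threshold > 0, binarize_threshold < 1)
  list(alpha = alpha, tau = tau, binarize_threshold = binarize_threshold)
}

# soft Dice with smoothing 1 in numerator and denominator (empty vs empty
# scores 1, i.e. loss 0)
soft_dice <- function(pred, target, smooth = 1) {
  (2 * tsum(pred * target) + smooth) /
    (tsum(pred) + tsum(target) + smooth)
}

bce_mean <- function(pred, target) {
  p <- tclamp(pred, P_EPS, 1 - P_EPS)
  -tmean(target * log(p) + (1 - target) * log(1 - p))
}

hard_dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' DSC + BCE compound segmentation loss
#'
#' `(1 - soft Dice) + mean binary cross-entropy`.
#'
#' @param pred probability map (values in `(0, 1)`).
#' @param target binary mask of the same shape.
#' @export
dsc_bce_loss <- function(pred, target) {
  if (!all(dim(agt_value(pred)) == dim(target)))
    stop("pred and target shapes differ")
  (1 - soft_dice(pred, target)) + bce_mean(pred, target)
}

# boundary of the binarized prediction: Canny edges dilated with a 3x3
# elliptical element (constant geometry; not differentiated)
pred_edge_indicator <- function(pred_value, threshold = 0.5) {
  bin <- as_mask(pred_value > threshold)
  if (sum(bin) == 0L) return(bin)
  edges <- canny_edges(bin + 0, sigma = 1, min_length = 1L)
  mask_dilate(edges, 1)
}

#' Contour loss against boundary pseudo-labels
#'
#' The predicted cortex mask is binarized, its Canny edges extracted and
#' dilated with a 3x3 elliptical element, and the BCE between that edge
#' indicator and the contour pseudo-labels is evaluated on the pixels
#' where the pseudo-labels are positive.  The edge geometry is constant
#' within the step; the gradient reaches the predicted probabilities at
#' those pixels straight-through.
#'
#' @param pred_cortex cortex probability map.
#' @param contour_pseudo binary contour pseudo-label map.
#' @param threshold binarization threshold for the edge geometry.
#' @export
contour_loss <- function(pred_cortex, contour_pseudo, threshold = 0.5) {
  cp <- as_mask(contour_pseudo)
  if (sum(cp) == 0L) return(0)
  v <- agt_value(pred_cortex)
  e <- pred_edge_indicator(v, threshold)
  sel <- cp == 1L
  # moderate clamp: a missed contour pixel costs -log(0.01), keeping the
  # term commensurate with the other loss components
  ec <- clamp(e[sel], 0.01, 0.99)
  val <- -mean(log(ec))        # targets are 1 on the pseudo-contour
  if (!is_agt(pred_cortex)) return(val)
  # gradient surrogate: a boundary passing through a contour pixel leaves
  # the probability there near 0.5, so drive p toward 0.5 on the
  # pseudo-contour; the (bounded) gradient positions the mask transition
  # on the annotated boundary while the value reports the hard-edge BCE
  agt_node(val, list(pred_cortex), function(g) {
    gx <- array(0, dim(v))
    gx[sel] <- g * 2 * (v[sel] - 0.5) / length(ec)
    list(gx)
  })
}

#' Self-hull shape loss
#'
#' One minus the soft Dice between the predicted cortex mask and the area
#' enclosed by its own concave hull: scattered or fragmented cortex
#' predictions leave holes inside the hull and are penalized.  An empty
#' prediction scores 1 by convention.
#'
#' @param pred_cortex cortex probability map.
#' @param threshold binarization threshold for the hull geometry.
#' @param concavity concave-hull tightness.
#' @export
self_hull_loss <- function(pred_cortex, threshold = 0.5, concavity = 2) {
  v <- agt_value(pred_cortex)
  bin <- as_mask(v > threshold)
  if (sum(bin) == 0L) return(1)
  hull <- hull_fill(despeckle(bin), concavity)
  1 - soft_dice(pred_cortex, hull)
}

# drop sub-speck components before hull construction: they barely move the
# hull but dominate its cost on noisy early-training masks
despeckle <- function(bin, min_area = 8L) {
  out <- mask_filter_area(bin, min_area)
  if (sum(out) == 0L) bin else out
}

#' Cross-hull consistency loss
#'
#' One minus the Dice overlap between the filled concave hulls of the
#' predicted cortex and vessel masks: the two outputs should enclose the
#' same region.  The hulls are constant geometry; gradients flow through
#' soft-Dice comparisons of each prediction against the other's hull.
#'
#' @param pred_cortex,pred_vessel probability maps.
#' @inheritParams self_hull_loss
#' @export
cross_hull_loss <- function(pred_cortex, pred_vessel, threshold = 0.5,
                            concavity = 2) {
  vc <- agt_value(pred_cortex); vv <- agt_value(pred_vessel)
  bc <- as_mask(vc > threshold); bv <- as_mask(vv > threshold)
  if (sum(bc) == 0L || sum(bv) == 0L) return(1)
  hc <- hull_fill(despeckle(bc), concavity)
  hv <- hull_fill(despeckle(bv), concavity)
  val <- 1 - hard_dice(hc, hv)
  if (!is_agt(pred_cortex) && !is_agt(pred_vessel)) return(val)
  # gradient through the cortex prediction only: pull the cortex mask
  # toward the vessel hull.  The vessel mask is sparse by nature -- asking
  # it to fill the cortex hull would fight its own segmentation term.
  surr <- 1 - soft_dice(pred_cortex, hv)
  agt_node(val, list(surr), function(g) list(g))
}

#' Excess loss: vessel activation outside the refined annotation
#'
#' Per batch item, the soft Dice between the complement of the refined
#' cortex annotation and the predicted vessel mask, passed through
#' `log(alpha * DSC + 1)` (natural log) and averaged.
#'
#' @param pred_vessel vessel probability maps: a matrix, an
#'   `(h, w, B)` array, or a list of matrices.
#' @param refined refined annotations in the same layout.
#' @param alpha penalty scale, default 10.
#' @export
excess_loss <- function(pred_vessel, refined, alpha = 10) {
  as_items <- function(x) {
    v <- agt_value(x)
    if (is.list(x)) x
    else if (length(dim(v)) == 3L)
      lapply(seq_len(dim(v)[3]), function(b)
        if (is_agt(x)) agt_index_plane(x, b) else v[, , b])
    else list(x)
  }
  pv <- as_items(pred_vessel)
  rf <- lapply(if (is.list(refined)) refined else as_items(refined),
               agt_value)
  if (length(pv) != length(rf)) stop("batch sizes differ")
  terms <- Map(function(p, y) {
    if (!all(dim(agt_value(p)) == dim(y))) stop("mask shapes differ")
    log(alpha * soft_dice(p, 1 - y) + 1)
  }, pv, rf)
  total <- Reduce(`+`, terms)
  total / length(terms)
}

# plane b of an (h, w, B) agt
agt_index_plane <- function(x, b) {
  v <- x$value
  out <- v[, , b]
  agt_node(out, list(x), function(g) {
    gx <- array(0, dim(v))
    gx[, , b] <- g
    list(gx)
  })
}

#' Total RGB-stage training loss
#'
#' The unweighted sum of the cortex DSC+BCE term (against the refined
#' annotation), the self-hull, contour, vessel DSC+BCE (against the
#' vessel pseudo-labels), cross-hull, and excess terms.
#'
#' @param outputs list with `cortex_prob` and `vessel_prob` maps.
#' @param pseudolabels list with `refined`, `contour`, and `vessel`
#'   masks.
#' @param config a [loss_config()].
#' @return list of the components (`l_ctx`, `l_self_hull`, `l_cont`,
#'   `l_vsl`, `l_cross_hull`, `l_excess`) and their sum `total`.
#' @export
total_rgb_loss <- function(outputs, pseudolabels, config = loss_config()) {
  for (nm in c("refined", "contour", "vessel"))
    if (is.null(pseudolabels[[nm]]))
      stop(sprintf("missing pseudo-label '%s'", nm))
  thr <- config$binarize_threshold
  comps <- list(
    l_ctx = dsc_bce_loss(outputs$cortex_prob, pseudolabels$refined),
    l_self_hull = self_hull_loss(outputs$cortex_prob, thr),
    l_cont = contour_loss(outputs$cortex_prob, pseudolabels$contour, thr),
    l_vsl = dsc_bce_loss(outputs$vessel_prob, pseudolabels$vessel),
    l_cross_hull = cross_hull_loss(outputs$cortex_prob,
                                   outputs$vessel_prob, thr),
    l_excess = excess_loss(outputs$vessel_prob, pseudolabels$refined,
                           config$alpha))
  comps$total <- Reduce(`+`, comps)
  comps
}

#' Supervised contrastive loss
#'
#' The supervised contrastive objective over L2-normalized embeddings:
#' each anchor attracts its same-label partners against all other samples,
#' with the sum over positives outside the log and temperature `tau`.
#' Anchors without a positive partner are skipped.
#'
#' @param embeddings `(dim, n)` matrix of unit-norm embedding columns.
#' @param labels length-`n` label vector.
#' @param tau temperature.
#' @export
supcon_loss <- function(embeddings, labels, tau = 0.1) {
  z <- agt_value(embeddings)
  n <- ncol(z)
  if (n < 2L) stop("need at least two samples")
  same <- outer(labels, labels, `==`) * 1
  diag(same) <- 0
  npos <- rowSums(same)
  anchors <- npos > 0
  if (!any(anchors)) stop("no anchor has a positive partner")
  offdiag <- 1 - diag(n)
  s <- agt_matmul_t(embeddings) / tau          # (n, n) similarity / tau
  e <- exp(s) * offdiag
  den <- agt_matmul(e, matrix(1, n, 1))        # (n, 1) denominators
  logden <- log(den)
  bcast <- agt_matmul(logden, matrix(1, 1, n)) # (n, n) row-wise broadcast
  wpos <- same / pmax(npos, 1) * anchors
  -tsum(wpos * (s - bcast)) / sum(anchors)
}

# t(Z) %*% Z with gradient
agt_matmul_t <- function(z) {
  v <- agt_value(z)
  out <- crossprod(v)
  if (!is_agt(z)) return(out)
  agt_node(out, list(z), function(g) list(v %*% (g + t(g))))
}

#' Masked cortex BCE against the adjusted ground truth
#'
#' BCE with target 1 on `inner` pixels and 0 on `outer` pixels; `unknown`
#' pixels are excluded from the mean entirely.
#'
#' @param pred_cortex cortex probability map.
#' @param adjusted integer adjusted-GT matrix (0 unknown, 1 inner,
#'   2 outer).
#' @export
masked_cortex_bce <- function(pred_cortex, adjusted) {
  sel <- adjusted != ADJ_UNKNOWN
  if (!any(sel)) {
    warning("adjusted ground truth is all-unknown; loss is 0")
    return(0)
  }
  target <- (adjusted == ADJ_INNER)[sel] * 1
  p <- agt_index(pred_cortex, sel)
  bce_mean(p, target)
}

#' Masked vessel BCE against pseudo-labels within the adjusted GT
#'
#' On `inner` pixels the target is the vessel pseudo-label; on `outer`
#' pixels any vessel activation is penalized (target 0); `unknown` pixels
#' and pseudo-labels outside `inner` are ignored.
#'
#' @param pred_vessel vessel probability map.
#' @param vessel_pseudo binary vessel pseudo-labels.
#' @param adjusted integer adjusted-GT matrix.
#' @export
masked_vessel_bce <- function(pred_vessel, vessel_pseudo, adjusted) {
  sel <- adjusted != ADJ_UNKNOWN
  if (!any(sel)) {
    warning("adjusted ground truth is all-unknown; loss is 0")
    return(0)
  }
  target <- (as_mask(vessel_pseudo) * (adjusted == ADJ_INNER))[sel]
  p <- agt_index(pred_vessel, sel)
  bce_mean(p, target)
}

flip_idx <- function(d, type) {
  switch(type,
         hflip = list(seq_len(d[1]), rev(seq_len(d[2]))),
         vflip = list(rev(seq_len(d[1])), seq_len(d[2])),
         rot180 = list(rev(seq_len(d[1])), rev(seq_len(d[2]))),
         identity = list(seq_len(d[1]), seq_len(d[2])),
         stop("unsupported transform: ", type))
}

transform_batch <- function(x, type) {
  v <- agt_value(x)
  d <- dim(v)
  ix <- flip_idx(d, type)
  out <- v[ix[[1]], ix[[2]], , , drop = FALSE]
  if (!is_agt(x)) return(out)
  agt_node(out, list(x), function(g)
    list(g[ix[[1]], ix[[2]], , , drop = FALSE]))  # flips are involutions
}

#' Equivariance regularizer
#'
#' Mean squared error between the network's prediction on transformed
#' inputs and the transformed prediction of the originals, averaged over
#' randomly sampled grid-invertible transforms (flips and 180-degree
#' rotation).
#'
#' @param model a `cortexnet`.
#' @param x input batch `(h, w, c, n)`.
#' @param modality input modality.
#' @param transform_set transforms to sample from.
#' @param n_transforms number of sampled transforms.
#' @param seed RNG seed for the sampling.
#' @param training batch-norm mode.
#' @export
equivariance_loss <- function(model, x, modality = "rgb",
                              transform_set = c("hflip", "vflip", "rot180"),
                              n_transforms = 1L, seed = 0L,
                              training = TRUE) {
  types <- withr::with_seed(seed,
    sample(transform_set, n_transforms, replace = TRUE))
  base <- net_forward(model, x, modality, training)$probs
  total <- 0
  for (tp in types) {
    xt <- transform_batch(x, tp)
    pt <- net_forward(model, xt, modality, training)$probs
    total <- total + tmean((pt - transform_batch(base, tp))^2)
  }
  total / length(types)
}
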