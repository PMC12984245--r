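#' Pseudo-label generation
#'
#' Turns weak supervision -- patch-based cortex annotations on RGB images
#' and sparse expert labels on HSI cubes -- into the dense training signals
#' the segmentation network needs: refined cortex masks, boundary contour
#' maps, line-operator vessel pseudo-labels, densified ground truth,
#' complementary background masks, and the three-way (inner/outer/unknown)
#' adjusted ground truth used for HSI fine-tuning.
#'
#' @name pseudolabel_gen
NULL

ADJ_UNKNOWN <- 0L
ADJ_INNER <- 1L
ADJ_OUTER <- 2L

#' Union mask of a patch annotation set
#'
#' @param ann a `patch_annotation_set` (see
#'   [generate_patch_annotations()]): `positive_patches` data.frame with
#'   `top`, `left`, `size`, plus `image_size`.
#' @return binary mask.
#' @export
build_patch_mask <- function(ann) {
  p <- ann$positive_patches
  if (is.null(p) || nrow(p) == 0L) stop("empty patch annotation set")
  m <- matrix(0L, ann$image_size[1], ann$image_size[2])
  for (i in seq_len(nrow(p))) {
    rs <- p$top[i]:(p$top[i] + p$size[i] - 1L)
    cs <- p$left[i]:(p$left[i] + p$size[i] - 1L)
    if (min(rs) < 1L || max(rs) > nrow(m) || min(cs) < 1L || max(cs) > ncol(m))
      stop("patch outside image bounds")
    m[rs, cs] <- 1L
  }
  m
}

# window sums of a k x k box at every valid top-left position, via a
# summed-area table; returns (h - k + 1) x (w - k + 1)
box_topleft_sum <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  S[(k + 1L):(h + 1L), (k + 1L):(w + 1L)] -
    S[1:(h - k + 1L), (k + 1L):(w + 1L)] -
    S[(k + 1L):(h + 1L), 1:(w - k + 1L)] +
    S[1:(h - k + 1L), 1:(w - k + 1L)]
}

# Chebyshev (box) dilation of a binary mask by radius r
box_dilate <- function(mask, r) {
  m <- as_mask(mask)
  if (r <= 0 || sum(m) == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  k <- 2L * as.integer(r) + 1L
  pad <- matrix(0L, h + k - 1L, w + k - 1L)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- m
  as_mask(box_topleft_sum(pad, k) > 0)
}

#' Sample negative patches outside an annotated region
#'
#' Draws non-overlapping square patches whose every pixel lies at least
#' `margin` pixels (Chebyshev distance) from the positive mask -- the
#' safety margin defaults to half the HSI frame height,
#' `floor(217 / 2) = 108`.  Placement is rejection-sampled over the set of
#' currently valid positions, so the result is deterministic under `seed`.
#'
#' @param mask binary positive (cortex) mask.
#' @param patch_size side length in pixels (default 217, the HSI height).
#' @param margin safety margin in pixels.
#' @param seed integer RNG seed.
#' @param max_patches optional cap on the number of patches.
#' @return data.frame with `top`, `left`, `size` (possibly 0 rows, with a
#'   warning, when no valid placement exists).
#' @export
sample_negative_patches <- function(mask, patch_size = 217L, margin = 108L,
                                    seed = 0L, max_patches = 64L) {
  m <- as_mask(mask)
  h <- nrow(m); w <- ncol(m)
  if (h < patch_size || w < patch_size)
    stop("image smaller than the patch size")
  forbidden <- box_dilate(m, margin)
  withr::with_seed(seed, {
    taken <- matrix(0L, h, w)
    out <- list()
    repeat {
      if (length(out) >= max_patches) break
      free <- box_topleft_sum(forbidden + taken, patch_size) == 0
      pos <- which(free, arr.ind = TRUE)
      if (nrow(pos) == 0L) break
      sel <- pos[sample.int(nrow(pos), 1L), ]
      out[[length(out) + 1L]] <- data.frame(top = sel[1], left = sel[2],
                                            size = patch_size)
      taken[sel[1]:(sel[1] + patch_size - 1L),
            sel[2]:(sel[2] + patch_size - 1L)] <- 1L
    }
    if (length(out) == 0L) {
      warning("no valid negative patch placement")
      return(data.frame(top = integer(), left = integer(), size = integer()))
    }
    do.call(rbind, out)
  })
}

# k-means over Lab pixel colors with subsampled fitting; returns per-pixel
# cluster ids (matrix) and the centroid matrix
cluster_colors <- function(img, k_clusters, sample_px = 20000L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  feats <- rgb_to_lab(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3])))
  n <- nrow(feats)
  idx <- if (n > sample_px) sample.int(n, sample_px) else seq_len(n)
  km <- suppressWarnings(kmeans(feats[idx, , drop = FALSE],
                                centers = k_clusters,
                                nstart = 8L, iter.max = 50L))
  assign <- assign_nearest(feats, km$centers)
  list(labels = matrix(assign, h, w), centers = km$centers, feats = feats)
}

#' Refine a patch-based cortex annotation into a full cortex mask
#'
#' Divides the image into K-means color clusters (Lab space), identifies
#' the clusters present inside the annotated patches -- treating the darker
#' ones as vessel-like and clusters with nearby centroids as cortex-like --
#' and grows the mask over connected regions of those clusters that touch
#' it, to a fixed point.  The result is closed morphologically and always
#' contains the closing of the input patch mask.  Clustering runs on a
#' downscaled copy (longest side `work_side`) for tractability; the
#' returned mask is at full resolution.
#'
#' @param rgb `(h, w, 3)` image in `[0, 1]`.
#' @param patch_mask binary annotation mask (union of patches).
#' @param k_clusters number of color clusters (>= 2).
#' @param centroid_mult a cluster counts as cortex-like when its centroid
#'   lies within `centroid_mult` times the mean color spread (RMS
#'   pixel-to-centroid distance) of the annotated clusters; the default 3
#'   admits illumination splits of annotated tissue while rejecting the
#'   chromatically distinct dura and drape clusters.
#' @param work_side internal working resolution (longest image side).
#' @param seed RNG seed for the clustering.
#' @return binary refined cortex mask, same size as `rgb`.
#' @export
refine_cortex_annotation <- function(rgb, patch_mask, k_clusters = 12L,
                                     centroid_mult = 3,
                                     work_side = 512L, seed = 0L) {
  if (k_clusters < 2L) stop("k_clusters must be at least 2")
  pm_full <- as_mask(patch_mask)
  if (sum(pm_full) == 0L) stop("patch mask is empty")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  f <- min(1, work_side / max(h, w))
  wd <- if (f < 1) c(round(h * f), round(w * f)) else c(h, w)
  img <- if (f < 1) resize_rgb(rgb, wd) else rgb
  pm <- if (f < 1) as_mask(resize_mat(pm_full, wd, "nearest")) else pm_full

  refined <- withr::with_seed(seed, {
    cl <- cluster_colors(img, k_clusters)
    in_counts <- tabulate(cl$labels[pm == 1L], nbins = k_clusters)
    in_mask_cl <- which(in_counts >= max(20L, 0.01 * sum(pm)))
    if (length(in_mask_cl) == 0L) in_mask_cl <- which.max(in_counts)
    lum <- rgb_luminance(img)
    med_lum <- median(lum[pm == 1L])
    cl_lum <- vapply(seq_len(k_clusters),
                     function(k) mean(lum[cl$labels == k]), numeric(1))
    # vessels propagate the annotation: the darker in-mask clusters
    vessel_like <- in_mask_cl[cl_lum[in_mask_cl] < med_lum - 0.02]
    dists <- as.matrix(dist(cl$centers))
    # cortex-like = within a multiple of the annotated clusters' own color
    # spread, so illumination splits of annotated tissue are admitted while
    # chromatically distinct distractors (dura, drapes) are not
    spread <- vapply(in_mask_cl, function(k) {
      members <- which(cl$labels == k)
      if (length(members) > 2000L) members <- members[seq(1, length(members),
                                                          length.out = 2000L)]
      sqrt(mean(rowSums(sweep(cl$feats[members, , drop = FALSE], 2,
                              cl$centers[k, ])^2)))
    }, numeric(1))
    thr <- centroid_mult * mean(spread)
    cortex_like <- which(apply(
      dists[, in_mask_cl, drop = FALSE] <= thr, 1, any))
    allowed_cl <- sort(unique(c(in_mask_cl, cortex_like)))
    allowed <- as_mask(matrix(cl$labels %in% allowed_cl, wd[1], wd[2]))
    vessel_px <- as_mask(matrix(cl$labels %in% vessel_like, wd[1], wd[2]))
    # a large background region can starve the clustering and merge two
    # distinct tissues into one in-mask cluster; split bimodal in-mask
    # clusters and reject the half that carries no patch annotation
    for (k in in_mask_cl) {
      members <- which(cl$labels == k)
      if (length(members) < 400L) next
      sub <- suppressWarnings(kmeans(cl$feats[members, , drop = FALSE],
                                     centers = 2L, nstart = 3L,
                                     iter.max = 30L))
      sep <- sqrt(sum((sub$centers[1, ] - sub$centers[2, ])^2))
      spread <- mean(sqrt(sub$withinss / pmax(sub$size, 1)))
      if (sep > 3 * spread) {
        pm_members <- pm[members] == 1L
        keep_sub <- which.max(c(sum(pm_members & sub$cluster == 1L),
                                sum(pm_members & sub$cluster == 2L)))
        reject <- members[sub$cluster != keep_sub]
        allowed[reject] <- 0L
        vessel_px[reject] <- 0L
      }
    }
    # absorb connected regions of admissible clusters that touch the mask
    # and are vascularized (vessel pixels mediate the propagation); a
    # component without vessel-like pixels never grows beyond the patches
    lab <- mask_label(allowed | pm, conn = 4L)
    touch <- setdiff(unique(lab[pm == 1L]), 0L)
    has_vessel <- intersect(touch, unique(lab[vessel_px == 1L]))
    grown <- as_mask(matrix(lab %in% has_vessel, wd[1], wd[2]))
    mask_close(grown, max(5, 0.01 * max(wd)))
  })
  if (f < 1) refined <- as_mask(resize_mat(refined, c(h, w), "nearest"))
  refined <- as_mask(ebi_data(EBImage::fillHull(refined)))
  as_mask(refined | mask_close(pm_full, 3))
}

#' Approximate the cortex perimeter from Canny edges and superpixels
#'
#' Computes Canny edges on the grayscale image, keeps those of sufficient
#' length, and searches the band between the 5%-eroded and 10%-dilated
#' versions of the refined mask (fractions of its equivalent-circle
#' diameter).  SLIC superpixels are grown outward from the eroded mask,
#' stopping at superpixels that contain a retained edge or leave the band;
#' the contour map is the retained edges adjacent to the grown region.
#'
#' @param rgb `(h, w, 3)` image in `[0, 1]` (a grayscale matrix is also
#'   accepted).
#' @param refined_mask binary cortex mask.
#' @param n_superpixels,compactness SLIC parameters.
#' @param min_edge_length minimum retained Canny edge length, px.
#' @param adjacency_px edges within this distance of the grown region
#'   form the contour; a tight radius rejects parallel distractor edges
#'   (e.g. the outer dura rim) that also fall inside the search band.
#' @return binary contour map.
#' @export
approximate_perimeter <- function(rgb, refined_mask, n_superpixels = 400L,
                                  compactness = 10,
                                  min_edge_length = 15L,
                                  adjacency_px = 3) {
  m <- as_mask(refined_mask)
  if (sum(m) == 0L) stop("refined mask is empty")
  gray <- if (is.matrix(rgb)) rgb else rgb_luminance(rgb)
  edges <- canny_edges(gray, min_length = min_edge_length)
  if (sum(edges) == 0L) return(edges)
  diam <- 2 * sqrt(sum(m) / pi)
  er <- mask_erode(m, 0.05 * diam)
  if (sum(er) == 0L) er <- m
  band <- as_mask(mask_dilate(m, 0.10 * diam) - er)

  spx <- slic_superpixels(if (is.matrix(rgb)) gray else rgb,
                          n_superpixels, compactness)
  S <- sqrt(length(m) / n_superpixels)
  edge_in_band <- as_mask(edges * band)
  sp_edge <- unique(spx[edge_in_band == 1L])
  outside <- as_mask(1L - (band | er))
  sp_sizes <- tabulate(spx, nbins = max(spx))
  sp_out_cnt <- tabulate(spx[outside == 1L], nbins = max(spx))
  sp_out <- which(sp_out_cnt > 0.2 * sp_sizes)

  # superpixel adjacency from 4-neighbour label pairs
  pairs <- rbind(cbind(as.vector(spx[-1, ]), as.vector(spx[-nrow(spx), ])),
                 cbind(as.vector(spx[, -1]), as.vector(spx[, -ncol(spx)])))
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  region <- sort(unique(spx[er == 1L]))
  blocked <- union(sp_edge, sp_out)
  repeat {
    nb <- unique(c(pairs[pairs[, 1] %in% region, 2],
                   pairs[pairs[, 2] %in% region, 1]))
    add <- setdiff(nb, union(region, blocked))
    if (length(add) == 0L) break
    region <- c(region, add)
  }
  grown <- as_mask(er | matrix(spx %in% region, nrow(m), ncol(m)))
  as_mask(edge_in_band * mask_dilate(grown, adjacency_px))
}

#' Build a bank of oriented line operators
#'
#' For each of `n` orientations (angular step `180 / n` degrees) and each
#' kernel size, a `k x k` kernel holding a centered straight line of the
#' given width: line pixels weigh `1 / n_line`, off-line pixels
#' `-1 / n_off`, so every kernel sums to zero.  Correlating the inverted
#' grayscale image with the bank scores elongated dark structures.
#'
#' @param k_thin,k_thick odd kernel sizes (>= 3) for capillaries and for
#'   thicker vessels.
#' @param n number of orientations.
#' @param line_width line thickness in pixels.
#' @return a `linear_operator_bank`: list of kernel lists per size.
#' @export
make_operator_bank <- function(k_thin = 7L, k_thick = 15L, n = 12L,
                               line_width = 1) {
  for (k in c(k_thin, k_thick))
    if (k < 3L || k %% 2L == 0L) stop("kernel sizes must be odd and >= 3")
  make_size <- function(k) {
    ctr <- (k + 1) / 2
    rows <- matrix(seq_len(k), k, k) - ctr
    cols <- matrix(seq_len(k), k, k, byrow = TRUE) - ctr
    lapply(seq_len(n) - 1L, function(i) {
      th <- i * pi / n
      # distance to the line through the center at angle th
      d <- abs(-sin(th) * cols + cos(th) * rows)
      # restrict to the line's extent so it runs side to side
      along <- abs(cos(th) * cols + sin(th) * rows)
      on_line <- d <= line_width / 2 + 1e-9 & along <= (k - 1) / 2 + 1e-9
      ker <- matrix(0, k, k)
      ker[on_line] <- 1 / sum(on_line)
      ker[!on_line] <- -1 / sum(!on_line)
      ker
    })
  }
  structure(list(n_orientations = n, line_width = line_width,
                 kernel_sizes = c(thin = k_thin, thick = k_thick),
                 kernels = list(thin = make_size(k_thin),
                                thick = make_size(k_thick))),
            class = "linear_operator_bank")
}

#' Detect vessels with an oriented line-operator bank
#'
#' Vessels are assumed darker than the surrounding cortex: the grayscale
#' image is inverted and correlated with every kernel in the bank; the
#' per-pixel response is the maximum over orientations and sizes.  Pixels
#' above the response quantile form the mask, and components smaller than
#' `min_area` are removed.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param bank a [make_operator_bank()].
#' @param threshold_quantile response quantile for binarization.
#' @param min_area minimum connected-component area, px.
#' @param response_type `"zero_mean"` correlates with the zero-mean
#'   kernels directly; `"local_std"` additionally normalizes the response
#'   by the local intensity standard deviation.
#' @return binary vessel mask.
#' @export
detect_vessels <- function(image, bank, threshold_quantile = 0.90,
                           min_area = 40L,
                           response_type = c("zero_mean", "local_std")) {
  response_type <- match.arg(response_type)
  img <- as.matrix(image)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("image must be scaled to [0, 1]")
  if (diff(range(img)) < .Machine$double.eps)
    return(matrix(0L, nrow(img), ncol(img)))
  inv <- 1 - img
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (size in names(bank$kernels)) {
    for (ker in bank$kernels[[size]]) {
      r <- ebi_data(EBImage::filter2(inv, ker, boundary = "replicate"))
      resp <- pmax(resp, r)
    }
  }
  if (response_type == "local_std") {
    k <- bank$kernel_sizes["thin"]
    mu <- ebi_data(EBImage::filter2(inv, matrix(1 / k^2, k, k),
                                    boundary = "replicate"))
    mu2 <- ebi_data(EBImage::filter2(inv^2, matrix(1 / k^2, k, k),
                                     boundary = "replicate"))
    resp <- resp / (sqrt(pmax(mu2 - mu^2, 0)) + 1e-3)
  }
  thr <- quantile(resp, threshold_quantile)
  mask_filter_area(as_mask(resp > thr), min_area, conn = 8L)
}

#' Vessel pseudo-labels for one scene
#'
#' Convenience wrapper applying [detect_vessels()] with the
#' modality-appropriate defaults: RGB uses larger kernels and minimum area
#' (vessels span more pixels at high resolution), HSI uses the red-visible
#' band of the calibrated cube as its grayscale source.
#'
#' @param x `(h, w, 3)` RGB array or an [hsi_cube()].
#' @param modality `"rgb"` or `"hsi"`.
#' @param threshold_quantile response quantile.
#' @param band HSI band used as the grayscale source (default 4, the
#'   red-visible band).
#' @export
vessel_pseudolabels <- function(x, modality = c("rgb", "hsi"),
                                threshold_quantile = 0.90, band = 4L) {
  modality <- match.arg(modality)
  if (modality == "rgb") {
    gray <- clamp(rgb_luminance(x), 0, 1)
    bank <- make_operator_bank(k_thin = 7L, k_thick = 15L)
    min_area <- 40L
  } else {
    stopifnot(inherits(x, "hsi_cube"))
    g <- x$data[band, , ]
    gray <- clamp((g - min(g)) / max(diff(range(g)), 1e-12), 0, 1)
    bank <- make_operator_bank(k_thin = 5L, k_thick = 11L)
    min_area <- 10L
  }
  detect_vessels(gray, bank, threshold_quantile, min_area)
}

#' Densify sparse ground truth by per-class morphological closing
#'
#' Each class is closed with an 11x11 elliptical structuring element;
#' pixels claimed by two or more classes after closing are reset to
#' unlabeled.  Closing never removes an input label and never invents a
#' class absent from the input.
#'
#' @param gt_sparse integer label mask (0 unlabeled, 1-4 classes).
#' @return densified integer label mask.
#' @export
densify_gt <- function(gt_sparse) {
  brush <- EBImage::makeBrush(11L, shape = "disc")
  h <- nrow(gt_sparse); w <- ncol(gt_sparse)
  closed <- list()
  for (cl in 1:4) {
    m <- as_mask(gt_sparse == cl)
    closed[[cl]] <- if (sum(m) > 0L)
      as_mask(ebi_data(EBImage::closing(m, brush))) else m
  }
  claims <- Reduce(`+`, closed)
  out <- matrix(CLASS_UNLABELED, h, w)
  for (cl in 1:4) out[closed[[cl]] == 1L & claims == 1L] <- cl
  out[gt_sparse != CLASS_UNLABELED] <- gt_sparse[gt_sparse != CLASS_UNLABELED]
  out
}

#' Complementary background mask from dissimilar clusters
#'
#' Clusters the pixels (K-means on Lab color for RGB input, on band
#' vectors for cubes), ranks clusters by the distance between their
#' centroid and the mean feature of cortical-labeled pixels (healthy,
#' tumor, vessel), and returns the `n_background` most distant clusters as
#' a background mask, excluding labeled pixels.
#'
#' @param x `(h, w, 3)` RGB array or an [hsi_cube()].
#' @param densified_gt integer label mask with cortical labels.
#' @param k_clusters number of clusters (> `n_background`).
#' @param n_background number of dissimilar clusters to keep.
#' @param seed RNG seed for the clustering.
#' @return binary background mask.
#' @export
complement_background <- function(x, densified_gt, k_clusters = 12L,
                                  n_background = 8L, seed = 0L) {
  if (k_clusters <= n_background)
    stop("k_clusters must exceed n_background")
  cortical <- densified_gt %in% c(CLASS_HEALTHY, CLASS_TUMOR, CLASS_VESSEL)
  if (!any(cortical)) stop("densified ground truth has no cortical labels")
  if (n_background == 0L)
    return(matrix(0L, nrow(densified_gt), ncol(densified_gt)))
  if (inherits(x, "hsi_cube")) {
    nb <- dim(x$data)[1]
    feats <- t(matrix(x$data, nrow = nb))
    h <- dim(x$data)[2]; w <- dim(x$data)[3]
  } else {
    feats <- rgb_to_lab(cbind(as.vector(x[, , 1]), as.vector(x[, , 2]),
                              as.vector(x[, , 3])))
    h <- dim(x)[1]; w <- dim(x)[2]
  }
  withr::with_seed(seed, {
    n <- nrow(feats)
    idx <- if (n > 20000L) sample.int(n, 20000L) else seq_len(n)
    km <- suppressWarnings(kmeans(feats[idx, , drop = FALSE],
                                  centers = k_clusters,
                                  nstart = 3L, iter.max = 30L))
    assign <- assign_nearest(feats, km$centers)
    ref <- colMeans(feats[which(cortical), , drop = FALSE])
    d <- sqrt(colSums((t(km$centers) - ref)^2))
    bg_cl <- order(d, decreasing = TRUE)[seq_len(n_background)]
    bg <- matrix(as.integer(assign %in% bg_cl), h, w)
    bg[densified_gt != CLASS_UNLABELED] <- 0L
    as_mask(bg)
  })
}

#' Three-way adjusted ground truth for HSI fine-tuning
#'
#' `inner` is the filled concave-hull region of the cortical labels
#' (healthy, tumor, vessel); `outer` is the union of dura labels and the
#' background mask, minus `inner` (inner takes precedence); everything
#' else is `unknown`.
#'
#' @param densified_gt integer label mask.
#' @param background_mask binary mask from [complement_background()].
#' @return integer matrix with codes 0 unknown, 1 inner, 2 outer.
#' @export
build_adjusted_gt <- function(densified_gt, background_mask) {
  cortical <- as_mask(densified_gt %in%
                        c(CLASS_HEALTHY, CLASS_TUMOR, CLASS_VESSEL))
  dim(cortical) <- dim(densified_gt)
  if (sum(cortical) == 0L)
    stop("densified ground truth has no cortical labels")
  inner <- hull_fill(cortical)
  outer <- as_mask((densified_gt == CLASS_DURA | as_mask(background_mask)) &
                     inner == 0L)
  out <- matrix(ADJ_UNKNOWN, nrow(densified_gt), ncol(densified_gt))
  out[outer == 1L] <- ADJ_OUTER
  out[inner == 1L] <- ADJ_INNER
  out
}

#' Crop and resize an RGB scene to the network's geometry
#'
#' Crops a window centered on the refined-mask centroid with the 217:409
#' aspect ratio, sized so the mask occupies `mask_fraction` of the window
#' (shifted/clipped to stay inside the frame; if the mask cannot fit at
#' that fraction the smallest aspect-correct window containing it is used,
#' with a warning), then resizes the image (bilinear) and all masks
#' (nearest) to `target` and rescales values to `[0, 1]`.
#'
#' @param rgb `(h, w, 3)` image.
#' @param refined_mask binary mask driving the crop.
#' @param masks named list of additional masks to transform identically.
#' @param target output `(height, width)`.
#' @param mask_fraction target mask area / window area.
#' @return list with `image`, `masks`, and the crop `window`
#'   (top, left, height, width).
#' @export
adapt_rgb_dataset <- function(rgb, refined_mask, masks = list(),
                              target = c(217L, 409L), mask_fraction = 0.20) {
  m <- as_mask(refined_mask)
  area <- sum(m)
  if (area == 0L) stop("refined mask is empty")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  aspect <- target[2] / target[1]
  wh <- sqrt(area / mask_fraction / aspect)
  ww <- wh * aspect
  pos <- mask_which(m)
  bbox <- c(min(pos[, 1]), max(pos[, 1]), min(pos[, 2]), max(pos[, 2]))
  need_h <- max(bbox[2] - bbox[1] + 1L, (bbox[4] - bbox[3] + 1L) / aspect)
  if (wh < need_h) {
    warning("mask exceeds the target fraction; using the smallest window ",
            "containing it")
    wh <- need_h; ww <- wh * aspect
  }
  if (wh > h || ww > w) {
    s <- min(h / wh, w / ww)
    wh <- wh * s; ww <- ww * s
  }
  wh <- round(wh); ww <- round(ww)
  ctr <- unname(colMeans(pos))
  top <- clamp(round(ctr[1] - wh / 2), 1, max(h - wh + 1, 1))
  left <- clamp(round(ctr[2] - ww / 2), 1, max(w - ww + 1, 1))
  win <- c(top = top, left = left, height = wh, width = ww)
  rows <- top:(top + wh - 1); cols <- left:(left + ww - 1)
  img <- clamp(resize_rgb(rgb[rows, cols, , drop = FALSE], target), 0, 1)
  out_masks <- lapply(masks, function(mm)
    as_mask(resize_mat(as_mask(mm)[rows, cols], target, "nearest")))
  list(image = img, masks = out_masks, window = win)
}
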