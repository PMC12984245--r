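#' Edge detection and superpixels
#'
#' Canny edge extraction and SLIC superpixels used by the perimeter
#' approximation and by the contour loss.  Neither is available from an
#' installed package, so both are implemented here: Canny as Gaussian
#' smoothing + Sobel gradients + non-maximum suppression + hysteresis, and
#' SLIC as localized k-means in (Lab, xy) space.
#'
#' @name edges
NULL

sobel_gradients <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/dcol
  gx <- ebi_data(EBImage::filter2(gray, t(kx), boundary = "replicate"))
  gy <- ebi_data(EBImage::filter2(gray, kx, boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection
#'
#' Thresholds default to 0.66 and 1.33 times the median gradient
#' magnitude; edges shorter than `min_length` pixels are dropped.
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param sigma Gaussian smoothing radius.
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL`
#'   picks the median-based defaults.
#' @param min_length minimum retained edge (connected component) length.
#' @return binary edge matrix.
#' @export
canny_edges <- function(gray, sigma = 1.4, low = NULL, high = NULL,
                        min_length = 15L) {
  g <- ebi_data(EBImage::gblur(as.matrix(gray), sigma = sigma,
                               boundary = "replicate"))
  sg <- sobel_gradients(g)
  mag <- sg$mag
  # FFT-based filtering leaves ~1e-15 dust on perfectly flat images
  if (max(mag) < 1e-8) return(matrix(0L, nrow(mag), ncol(mag)))
  med <- median(mag)
  # noise-free images leave only numerical dust away from real edges;
  # fall back to a fraction of the peak gradient
  if (med < 1e-3 * max(mag)) med <- 0.15 * max(mag)
  if (is.null(low)) low <- 0.66 * med
  if (is.null(high)) high <- 1.33 * med

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(sg$gy, sg$gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    n1 <- shift_mat(mag, o[1], o[2])
    n2 <- shift_mat(mag, -o[1], -o[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(0L, nrow(mag), ncol(mag)))
  lab <- ebi_data(EBImage::bwlabel(as_mask(weak)))
  keep <- unique(lab[strong & lab > 0])
  edges <- as_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
  if (min_length > 1L) edges <- mask_filter_area(edges, min_length, conn = 8L)
  edges
}

#' SLIC superpixel segmentation
#'
#' Localized k-means over (L, a, b, row, col) features; the spatial
#' coordinates are weighted by `compactness / S` with `S` the grid step.
#'
#' @param img `(h, w, 3)` RGB array in `[0, 1]`, or a grayscale matrix
#'   (used as all three channels).
#' @param n_superpixels approximate number of superpixels.
#' @param compactness spatial regularity weight.
#' @param iterations assignment/update sweeps.
#' @return integer label matrix (labels `1..k`).
#' @export
slic_superpixels <- function(img, n_superpixels = 400L, compactness = 10,
                             iterations = 5L) {
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  h <- dim(img)[1]; w <- dim(img)[2]
  lab <- rgb_to_lab(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3])))
  S <- sqrt(h * w / n_superpixels)
  ctr_r <- seq(S / 2, h, by = S)
  ctr_c <- seq(S / 2, w, by = S)
  centers <- cbind(0, 0, 0,
                   rep(ctr_r, times = length(ctr_c)),
                   rep(ctr_c, each = length(ctr_r)))
  idx0 <- (pmin(round(centers[, 5]), w) - 1) * h + pmin(round(centers[, 4]), h)
  centers[, 1:3] <- lab[idx0, , drop = FALSE]
  assign <- NULL
  for (it in seq_len(iterations)) {
    assign <- slic_assign(lab, h, w, centers, S, compactness)
    # unassigned pixels (outside every search window) get nearest center
    miss <- which(assign == 0L)
    if (length(miss) > 0L) {
      rr <- (miss - 1L) %% h + 1L; cc <- (miss - 1L) %/% h + 1L
      assign[miss] <- assign_nearest(cbind(rr, cc),
                                     centers[, 4:5, drop = FALSE])
    }
    for (k in seq_len(nrow(centers))) {
      sel <- which(assign == k)
      if (length(sel) == 0L) next
      rr <- (sel - 1L) %% h + 1L; cc <- (sel - 1L) %/% h + 1L
      centers[k, ] <- c(colMeans(lab[sel, , drop = FALSE]),
                        mean(rr), mean(cc))
    }
  }
  matrix(assign, h, w)
}
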