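#' Concave hulls of pixel sets
#'
#' The shape-aware losses and the adjusted ground truth rely on the filled
#' concave hull of a pixel set: a tight, possibly non-convex polygon around
#' the set's boundary points.  The hull is computed by iterative edge
#' digging on the convex hull (an edge is split toward its nearest interior
#' point when the edge is long relative to that distance, controlled by a
#' concavity parameter), falling back to the convex hull for fewer than 10
#' points.  No installed package provides a concave hull, so it is
#' implemented here.
#'
#' @name concave_hull
NULL

# squared distance from points (n x 2) to segment a-b
dist2_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(rowSums(sweep(pts, 2, a)^2))
  t <- clamp(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2,
             0, 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
  rowSums((pts - proj)^2)
}

#' Concave hull polygon of a point set
#'
#' @param pts numeric matrix `(n, 2)` of (row, col) coordinates.
#' @param concavity edge-digging threshold; larger values give a tighter,
#'   more concave outline.  2 is the package default throughout.
#' @param max_points boundary points are subsampled to at most this many
#'   before hull construction (hulls are geometry targets, not gradients,
#'   so light subsampling is harmless).
#' @return ordered polygon vertices `(m, 2)` (not closed).
#' @export
concave_hull <- function(pts, concavity = 2, max_points = 150L) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3L) return(pts)
  if (n > max_points) {
    idx <- round(seq(1L, n, length.out = max_points))
    pts <- pts[unique(idx), , drop = FALSE]
    n <- nrow(pts)
  }
  ch <- grDevices::chull(pts[, 2], pts[, 1])  # chull takes (x, y)
  hull <- pts[ch, , drop = FALSE]
  if (n < 10L) return(hull)
  in_hull <- rep(FALSE, n)
  in_hull[ch] <- TRUE

  # iterative digging: split long edges toward their nearest interior point
  changed <- TRUE
  guard <- 0L
  while (changed && guard < 30L) {
    guard <- guard + 1L
    changed <- FALSE
    i <- 1L
    while (i <= nrow(hull)) {
      a <- hull[i, ]
      b <- hull[if (i == nrow(hull)) 1L else i + 1L, ]
      edge_len2 <- sum((a - b)^2)
      cand <- which(!in_hull)
      if (length(cand) == 0L) break
      d2 <- dist2_to_segment(pts[cand, , drop = FALSE], a, b)
      j <- which.min(d2)
      if (edge_len2 > concavity^2 * d2[j] && d2[j] > 0) {
        p_idx <- cand[j]
        hull <- rbind(hull[seq_len(i), , drop = FALSE], pts[p_idx, ],
                      if (i < nrow(hull))
                        hull[(i + 1L):nrow(hull), , drop = FALSE])
        in_hull[p_idx] <- TRUE
        changed <- TRUE
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  hull
}

#' Filled concave-hull region of a binary mask
#'
#' Computes the concave hull of the mask's boundary pixels and rasterizes
#' its interior (union with the mask itself, so the region always contains
#' the input).  An empty mask gives an empty region.
#'
#' @param mask binary matrix.
#' @param concavity see [concave_hull()].
#' @return binary matrix of the filled hull region.
#' @export
hull_fill <- function(mask, concavity = 2) {
  m <- as_mask(mask)
  if (sum(m) == 0L) return(m)
  bd <- boundary_4(m)
  pts <- mask_which(bd)
  if (nrow(pts) < 3L) return(m)
  poly <- concave_hull(pts, concavity)
  if (nrow(poly) < 3L) return(m)
  # rasterize: point-in-polygon test on the bounding-box grid
  r0 <- max(1L, min(poly[, 1]) - 1L); r1 <- min(nrow(m), max(poly[, 1]) + 1L)
  c0 <- max(1L, min(poly[, 2]) - 1L); c1 <- min(ncol(m), max(poly[, 2]) + 1L)
  grid <- cbind(rep(r0:r1, times = c1 - c0 + 1L),
                rep(c0:c1, each = r1 - r0 + 1L))
  bnd <- rbind(poly, poly[1L, ])
  inside <- mgcv::in.out(bnd, grid)
  fill <- m
  fill[grid[inside, , drop = FALSE]] <- 1L
  as_mask(fill | m)
}
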