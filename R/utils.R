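#' @useDynLib cortexfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans quantile rnorm runif sd median ecdf approx aggregate
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
as_mask <- function(x) {
  m <- (as.matrix(x) > 0) * 1L
  storage.mode(m) <- "integer"
  m
}

# EBImage returns Image objects; strip back to plain matrices/arrays
ebi_data <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

# odd-sized disc brush with radius >= r (EBImage brushes must be odd)
disc_brush <- function(r) {
  size <- max(3L, 2L * as.integer(round(r)) + 1L)
  EBImage::makeBrush(size, shape = "disc")
}

mask_erode <- function(mask, r) {
  if (r <= 0) return(as_mask(mask))
  as_mask(ebi_data(EBImage::erode(as_mask(mask), disc_brush(r))))
}

mask_dilate <- function(mask, r) {
  if (r <= 0) return(as_mask(mask))
  as_mask(ebi_data(EBImage::dilate(as_mask(mask), disc_brush(r))))
}

mask_close <- function(mask, r) {
  if (r <= 0) return(as_mask(mask))
  as_mask(ebi_data(EBImage::closing(as_mask(mask), disc_brush(r))))
}

# connected components; conn = 4 or 8
mask_label <- function(mask, conn = 4L) {
  m <- as_mask(mask)
  if (conn == 4L) {
    # EBImage::bwlabel is 8-connected; enforce 4-connectivity by breaking
    # diagonal-only links through a two-pass union on the 8-labelling
    lab <- label_components_4(m)
  } else {
    lab <- ebi_data(EBImage::bwlabel(m))
  }
  storage.mode(lab) <- "integer"
  lab
}

# drop connected components smaller than min_area
mask_filter_area <- function(mask, min_area, conn = 8L) {
  lab <- mask_label(mask, conn)
  if (max(lab) == 0L) return(as_mask(mask * 0))
  keep <- which(tabulate(lab[lab > 0L]) >= min_area)
  as_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
}

# Euclidean distance from every pixel to the nearest pixel of `set`
dist_to_set <- function(set) {
  s <- as_mask(set)
  if (sum(s) == 0L) return(matrix(Inf, nrow(s), ncol(s)))
  ebi_data(EBImage::distmap(1L - s, metric = "euclidean"))
}

# bilinear / nearest resize of a plain (h, w) matrix
resize_mat <- function(m, dims, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- ebi_data(EBImage::resize(as.matrix(m), w = dims[1], h = dims[2],
                                  filter = filt))
  out
}

resize_rgb <- function(img, dims, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  out <- array(0, c(dims[1], dims[2], dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- resize_mat(img[, , k], dims, method)
  out
}

# luminance of an (h, w, 3) array, ITU-R 601 weights
rgb_luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# RGB -> CIE Lab (D65), on an n x 3 matrix of [0,1] values
rgb_to_lab <- function(rgbmat) {
  conv <- grDevices::convertColor(rgbmat, from = "sRGB", to = "Lab")
  conv
}

# positions (row, col) of nonzero pixels as an n x 2 matrix
mask_which <- function(mask) {
  which(as_mask(mask) > 0L, arr.ind = TRUE)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
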