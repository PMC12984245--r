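#' Synthetic craniotomy scene generation
#'
#' Generates craniotomy-like RGB images and matching 25-band hyperspectral
#' cubes with known cortex / vessel / tumor / dura truth, plus raw
#' snapshot-mosaic frames, sparse ground truth in the style of the
#' semi-automatic annotation tool, weak patch annotations, and controllably
#' flawed tissue-classifier outputs.  The scenes emulate the statistics the
#' segmentation method relies on -- a single irregular bright cortex region
#' surrounded by a dura ring and darker drapes, with dark curvilinear
#' vessels inside the cortex -- without attempting photorealism.
#'
#' @name synthetic_scene
NULL

#' Default per-class 25-band reflectance signatures
#'
#' Flat-ish spectra in `[0, 1]` with a fixed brightness ordering:
#' dura > healthy > tumor > vessel > drape.  The vessel signature sits at
#' least 0.15 below healthy and tumor in every band, so vessels remain
#' darker than the surrounding cortex after illumination texture and noise.
#'
#' @return named list of numeric 25-vectors
#'   (healthy, tumor, vessel, dura, drape).
#' @export
default_signatures <- function() {
  b <- seq(0, 1, length.out = 25)
  list(
    healthy = 0.55 + 0.08 * b,                      # bright cortex
    tumor   = 0.46 + 0.02 * b + 0.06 * exp(-((b - 0.35) / 0.12)^2),
    vessel  = 0.22 + 0.05 * b,                      # dark, blood absorption
    dura    = 0.68 + 0.05 * b,
    drape   = 0.12 + 0.02 * b
  )
}

#' Synthetic scene configuration
#'
#' @param seed integer RNG seed; equal seeds give bit-identical scenes.
#' @param rgb_size `(height, width)` of the RGB capture, default
#'   `c(1080, 1920)`.
#' @param hsi_size `(height, width)` of the demosaicked cube; fixed at
#'   `c(217, 409)`.
#' @param n_vessels number of vessel strokes.
#' @param vessel_width_range vessel widths in HSI pixels, `[1, 8]`.
#' @param tumor_present draw a tumor blob with its own signature.
#' @param class_signatures list of 25-band reflectance vectors in `[0, 1]`,
#'   see [default_signatures()].
#' @param noise_sd Gaussian reflectance noise, must keep the 3-sigma
#'   vessel/cortex contrast margin (`<= 0.04`).
#' @export
scene_config <- function(seed = 0L, rgb_size = c(1080L, 1920L),
                         hsi_size = c(217L, 409L), n_vessels = 6L,
                         vessel_width_range = c(1, 8),
                         tumor_present = TRUE,
                         class_signatures = default_signatures(),
                         noise_sd = 0.01) {
  if (!identical(as.integer(hsi_size), c(217L, 409L)))
    stop("hsi_size is fixed at (217, 409)")
  if (length(rgb_size) != 2L || any(rgb_size < 64))
    stop("invalid rgb_size")
  for (nm in names(class_signatures)) {
    sig <- class_signatures[[nm]]
    if (length(sig) != 25L)
      stop(sprintf("signature '%s' must have 25 bands", nm))
    if (any(sig < 0 | sig > 1))
      stop(sprintf("signature '%s' must lie in [0, 1]", nm))
  }
  if (noise_sd < 0 || noise_sd > 0.04)
    stop("noise_sd must be in [0, 0.04]")
  structure(list(seed = as.integer(seed), rgb_size = as.integer(rgb_size),
                 hsi_size = as.integer(hsi_size),
                 n_vessels = as.integer(n_vessels),
                 vessel_width_range = vessel_width_range,
                 tumor_present = isTRUE(tumor_present),
                 class_signatures = class_signatures,
                 noise_sd = noise_sd),
            class = "scene_config")
}

# star-shaped blob: radius R0 * (1 + sum a_k cos(k theta + phi_k)),
# rasterized on an (h, w) grid; center/R0 in pixel units of that grid
rasterize_blob <- function(h, w, cy, cx, r0, amps, phases, ks) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  th <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, Map(function(a, p, k) a * cos(k * th + p),
                                   amps, phases, ks), accumulate = FALSE))
  m <- as_mask(sqrt(dy^2 + dx^2) <= rad)
  # guarantee a single filled 4-connected component
  m <- as_mask(ebi_data(EBImage::fillHull(m)))
  lab <- mask_label(m, 4L)
  if (max(lab) > 1L) {
    keep <- which.max(tabulate(lab[lab > 0L]))
    m <- as_mask(lab == keep)
  }
  m
}

# quadratic Bezier through p0, p1 (control), p2; returns dense points (t x 2)
bezier_points <- function(p0, p1, p2, n = 400L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

rasterize_strokes <- function(h, w, strokes, scale = 1) {
  out <- matrix(0L, h, w)
  for (s in strokes) {
    pts <- bezier_points(s$p0 * scale, s$p1 * scale, s$p2 * scale,
                         n = max(200L, ceiling(400 * scale)))
    pts <- round(pts)
    keep <- pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0L) next
    m <- matrix(0L, h, w)
    m[cbind(pts[, 1], pts[, 2])] <- 1L
    wd <- s$width * scale
    if (wd > 1) m <- mask_dilate(m, wd / 2)
    out <- as_mask(out | m)
  }
  out
}

# low-frequency multiplicative illumination field in [-amp, amp]
illumination_field <- function(h, w, amp = 0.04) {
  coarse <- matrix(runif(9 * 9, -1, 1), 9, 9)
  amp * resize_mat(coarse, c(h, w), "bilinear")
}

#' Generate one synthetic craniotomy scene
#'
#' Builds the scene geometry analytically (polar-harmonic cortex and tumor
#' blobs, quadratic Bezier vessel strokes) and rasterizes it at both the
#' HSI and RGB resolutions, so the two modalities share the exact same
#' anatomy.  The cube is composed per pixel as class signature times a
#' smooth illumination field plus Gaussian noise; the raw mosaic frame is
#' the inverse-demosaicked synthetic radiance so the preprocessing chain
#' round-trips; white/dark reference cubes are included.
#'
#' @param config a [scene_config()].
#' @return a `scene_pack` list: `rgb` (h, w, 3), `cube` ([hsi_cube()]),
#'   `raw` (mosaic matrix), `white`/`dark` reference cubes, `gt_sparse`,
#'   `class_map`, `cortex_gold`, `vessel_truth` (HSI resolution),
#'   `rgb_cortex_gold`, `rgb_vessel_truth`, and the `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  hh <- config$hsi_size[1]; hw <- config$hsi_size[2]
  rh <- config$rgb_size[1]; rw <- config$rgb_size[2]
  scale <- mean(c(rh / hh, rw / hw))

  # cortex blob: area fraction drawn in [0.12, 0.22] of the HSI frame
  frac <- runif(1, 0.12, 0.22)
  ks <- 2:5
  amps <- runif(4, 0, 0.3 / seq_along(ks))
  phases <- runif(4, 0, 2 * pi)
  r0 <- sqrt(frac * hh * hw / (pi * (1 + sum(amps^2) / 2)))
  cy <- hh / 2 + runif(1, -0.08, 0.08) * hh
  cx <- hw / 2 + runif(1, -0.08, 0.08) * hw
  cortex <- rasterize_blob(hh, hw, cy, cx, r0, amps, phases, ks)
  rgb_cortex <- rasterize_blob(rh, rw, cy * rh / hh, cx * rw / hw,
                               r0 * scale, amps, phases, ks)

  # tumor blob inside the cortex, away from its boundary
  tumor <- matrix(0L, hh, hw); rgb_tumor <- matrix(0L, rh, rw)
  if (config$tumor_present) {
    core <- mask_erode(cortex, r0 * 0.35)
    if (sum(core) == 0L) core <- mask_erode(cortex, 3)
    pos <- mask_which(core)
    ctr <- pos[sample.int(nrow(pos), 1L), ]
    t_r0 <- r0 * runif(1, 0.28, 0.38)
    t_amps <- runif(3, 0, 0.25 / (1:3))
    t_phases <- runif(3, 0, 2 * pi)
    tumor <- rasterize_blob(hh, hw, ctr[1], ctr[2], t_r0,
                            t_amps, t_phases, 2:4) * cortex
    rgb_tumor <- rasterize_blob(rh, rw, ctr[1] * rh / hh, ctr[2] * rw / hw,
                                t_r0 * scale, t_amps, t_phases, 2:4) *
      rgb_cortex
  }

  # vessels: quadratic Bezier strokes between points inside the cortex
  interior <- mask_erode(cortex, 4)
  if (sum(interior) == 0L) interior <- cortex
  pos <- mask_which(interior)
  strokes <- vector("list", config$n_vessels)
  for (i in seq_len(config$n_vessels)) {
    idx <- sample.int(nrow(pos), 2L)
    p0 <- as.numeric(pos[idx[1], ]); p2 <- as.numeric(pos[idx[2], ])
    mid <- (p0 + p2) / 2
    d <- p2 - p0
    perp <- c(-d[2], d[1]) / max(sqrt(sum(d^2)), 1)
    p1 <- mid + perp * rnorm(1, 0, sqrt(sum(d^2)) / 4)
    strokes[[i]] <- list(p0 = p0, p1 = p1, p2 = p2,
                         width = runif(1, config$vessel_width_range[1],
                                       config$vessel_width_range[2]))
  }
  vessels <- as_mask(rasterize_strokes(hh, hw, strokes) * cortex)
  rgb_vessels <- as_mask(rasterize_strokes(rh, rw, strokes, scale) *
                           rgb_cortex)

  # dura ring around the cortex
  dura <- as_mask(mask_dilate(cortex, 14) - cortex)
  rgb_dura <- as_mask(mask_dilate(rgb_cortex, 14 * scale) - rgb_cortex)

  class_map <- matrix(CLASS_UNLABELED, hh, hw)
  class_map[dura == 1L] <- CLASS_DURA
  class_map[cortex == 1L] <- CLASS_HEALTHY
  class_map[tumor == 1L] <- CLASS_TUMOR
  class_map[vessels == 1L] <- CLASS_VESSEL
  rgb_class_map <- matrix(CLASS_UNLABELED, rh, rw)
  rgb_class_map[rgb_dura == 1L] <- CLASS_DURA
  rgb_class_map[rgb_cortex == 1L] <- CLASS_HEALTHY
  rgb_class_map[rgb_tumor == 1L] <- CLASS_TUMOR
  rgb_class_map[rgb_vessels == 1L] <- CLASS_VESSEL

  sig <- config$class_signatures
  field <- illumination_field(hh, hw)
  cube_data <- array(0, c(25L, hh, hw))
  sig_of <- function(code) switch(as.character(code),
                                  "0" = sig$drape, "1" = sig$healthy,
                                  "2" = sig$tumor, "3" = sig$vessel,
                                  "4" = sig$dura)
  base <- matrix(0, hh, hw)
  for (b in 1:25) {
    for (code in 0:4) base[class_map == code] <- sig_of(code)[b]
    cube_data[b, , ] <- pmax(base * (1 + field) +
                               rnorm(hh * hw, 0, config$noise_sd), 0)
  }
  cube <- hsi_cube(cube_data, calibrated = TRUE)

  # references and the raw mosaic radiance frame
  gains <- 0.85 + 0.1 * sin(seq(0, pi, length.out = 25))
  white_data <- array(rep(gains, hh * hw), c(25L, hh, hw))
  dark_data <- array(0.05, c(25L, hh, hw))
  radiance <- cube_data * (white_data - dark_data) + dark_data
  raw <- mosaic_frame(hsi_cube(radiance, calibrated = FALSE))

  # RGB rendering from per-class colors, same illumination style
  cols <- list("0" = c(0.20, 0.34, 0.40), "1" = c(0.76, 0.55, 0.50),
               "2" = c(0.64, 0.44, 0.56), "3" = c(0.33, 0.10, 0.10),
               "4" = c(0.86, 0.62, 0.66))
  rgb_field <- illumination_field(rh, rw)
  rgb <- array(0, c(rh, rw, 3L))
  chan <- matrix(0, rh, rw)
  for (k in 1:3) {
    for (code in 0:4)
      chan[rgb_class_map == code] <- cols[[as.character(code)]][k]
    rgb[, , k] <- clamp(chan * (1 + rgb_field) +
                          rnorm(rh * rw, 0, config$noise_sd), 0, 1)
  }

  pack <- structure(list(rgb = rgb, cube = cube, raw = raw,
                         white = hsi_cube(white_data, calibrated = FALSE),
                         dark = hsi_cube(dark_data, calibrated = FALSE),
                         class_map = class_map,
                         cortex_gold = cortex, vessel_truth = vessels,
                         rgb_class_map = rgb_class_map,
                         rgb_cortex_gold = rgb_cortex,
                         rgb_vessel_truth = rgb_vessels,
                         config = config),
                    class = "scene_pack")
  pack$gt_sparse <- generate_sparse_gt(pack, fraction = 0.3,
                                       seed = config$seed + 1L)
  pack
}

#' Sparse ground truth by compact subsampling of the truth classes
#'
#' Emulates the sparse annotation style of the semi-automatic labeling tool:
#' for each class present in the scene, a few compact blobs covering
#' approximately `fraction` of that class's area are labeled, with zero
#' label noise.
#'
#' @param pack a `scene_pack`.
#' @param fraction target labeled fraction per class, in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return integer label mask at HSI resolution.
#' @export
generate_sparse_gt <- function(pack, fraction = 0.3, seed = 0L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  cm <- pack$class_map
  if (fraction == 1) return(cm)
  withr::with_seed(seed, {
    out <- matrix(CLASS_UNLABELED, nrow(cm), ncol(cm))
    for (cl in c(CLASS_HEALTHY, CLASS_TUMOR, CLASS_VESSEL, CLASS_DURA)) {
      region <- as_mask(cm == cl)
      area <- sum(region)
      if (area == 0L) next
      target <- fraction * area
      pos <- mask_which(region)
      nb <- min(3L, max(1L, nrow(pos) %/% 50L))
      ctrs <- pos[sample.int(nrow(pos), nb), , drop = FALSE]
      r <- sqrt(target / (nb * pi))
      sel <- matrix(FALSE, nrow(cm), ncol(cm))
      for (iter in 1:8) {
        sel[] <- FALSE
        for (i in seq_len(nb)) {
          dy <- row(cm) - ctrs[i, 1]; dx <- col(cm) - ctrs[i, 2]
          sel <- sel | (dy^2 + dx^2 <= r^2)
        }
        sel_area <- sum(sel & region == 1L)
        if (sel_area >= target * 0.85 && sel_area <= target * 1.25) break
        r <- r * sqrt(target / max(sel_area, 1))
      }
      out[sel & region == 1L] <- cl
    }
    out
  })
}

#' Weak patch annotations of the cortex on the RGB image
#'
#' Samples axis-aligned square patches fully inside the true cortex region
#' until roughly `coverage` of the cortex area is covered, mimicking the
#' rapid patch-based manual annotation of the exposed brain surface.
#'
#' @param pack a `scene_pack`.
#' @param coverage target fraction of the cortex covered by patches.
#' @param size_range patch side lengths in RGB pixels.
#' @param seed integer RNG seed.
#' @return a `patch_annotation_set`: list with `positive_patches`
#'   (data.frame top/left/size) and `image_size`.
#' @export
generate_patch_annotations <- function(pack, coverage = 0.45,
                                       size_range = NULL, seed = 0L) {
  gold <- pack$rgb_cortex_gold
  h <- nrow(gold); w <- ncol(gold)
  if (is.null(size_range)) size_range <- round(c(0.04, 0.11) * h)
  withr::with_seed(seed, {
    inside <- dist_to_set(1L - gold)   # distance to non-cortex
    covered <- matrix(0L, h, w)
    patches <- list()
    target <- coverage * sum(gold)
    for (iter in 1:400) {
      if (sum(covered) >= target) break
      size <- round(runif(1, size_range[1], size_range[2]))
      half <- ceiling(size * sqrt(2) / 2)  # circumradius of the square
      ok <- inside > half
      pos <- which(ok, arr.ind = TRUE)
      if (nrow(pos) == 0L) break
      ctr <- pos[sample.int(nrow(pos), 1L), ]
      top <- max(1L, ctr[1] - size %/% 2L)
      left <- max(1L, ctr[2] - size %/% 2L)
      top <- min(top, h - size + 1L); left <- min(left, w - size + 1L)
      covered[top:(top + size - 1L), left:(left + size - 1L)] <- 1L
      patches[[length(patches) + 1L]] <-
        data.frame(top = top, left = left, size = size)
    }
    structure(list(positive_patches = do.call(rbind, patches),
                   image_size = c(h, w)),
              class = "patch_annotation_set")
  })
}

#' Flawed four-class tissue probabilities for fusion experiments
#'
#' Emulates an imperfect per-pixel tissue classifier: for each pixel the
#' predicted class is drawn from the confusion-matrix row of its true class
#' (drape/unlabeled pixels behave as dura), and a probability vector
#' favouring that class is sampled.  Per-pixel probabilities sum to 1.
#'
#' @param pack a `scene_pack`.
#' @param confusion 4x4 row-stochastic matrix over
#'   (healthy, tumor, vessel, dura); row i gives the predicted-class
#'   distribution for true class i.
#' @param seed integer RNG seed.
#' @return array `(h, w, 4)` of probabilities.
#' @export
generate_flawed_probs <- function(pack, confusion = diag(4), seed = 0L) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4L, 4L)) ||
      any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion must be a 4x4 row-stochastic matrix")
  cm <- pack$class_map
  h <- nrow(cm); w <- ncol(cm)
  withr::with_seed(seed, {
    true4 <- cm
    true4[true4 == CLASS_UNLABELED] <- CLASS_DURA  # drapes behave like dura
    n <- h * w
    u <- runif(n)
    cum <- t(apply(confusion, 1, cumsum))
    drawn <- integer(n)
    for (cl in 1:4) {
      idx <- which(true4 == cl)
      drawn[idx] <- findInterval(u[idx], c(0, cum[cl, ]),
                                 rightmost.closed = TRUE)
    }
    drawn <- pmin(pmax(drawn, 1L), 4L)
    probs <- matrix(runif(n * 4, 0.01, 0.10), n, 4)
    probs[cbind(seq_len(n), drawn)] <- runif(n, 0.60, 0.90)
    probs <- probs / rowSums(probs)
    array(probs, c(h, w, 4L))
  })
}
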