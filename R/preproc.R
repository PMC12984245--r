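#' Snapshot-mosaic HSI preprocessing
#'
#' Demosaicking of 5x5 snapshot-mosaic frames into 25-band cubes,
#' white/dark reflectance calibration, spectral cross-talk correction,
#' pseudo-RGB reconstruction, per-band min-max normalization, and spatial
#' adaptation of foreign cube sizes to the network's 217x409 input.
#'
#' @name hsi_preproc
NULL

#' Nominal band-center wavelengths of the snapshot camera
#'
#' The camera captures 25 near-infrared bands between 665 and 960 nm; only
#' three band centers are documented (band 4 at 712.4 nm, band 20 at
#' 913.7 nm, band 23 at 940.9 nm).  The remaining centers are synthetic,
#' interpolated piecewise-linearly through those anchors.
#'
#' @return ascending numeric vector of 25 wavelengths in nm.
#' @export
snapshot_wavelengths <- function() {
  anchors_band <- c(1, 4, 20, 23, 25)
  anchors_nm <- c(665, 712.4, 913.7, 940.9, 960)
  approx(anchors_band, anchors_nm, xout = 1:25)$y
}

#' Documented pseudo-RGB band assignment of the snapshot camera
#'
#' The instrument's red channel is its fourth band (712.4 nm, the only band
#' in the visible red); green is approximated by band 23 (940.9 nm, second
#' harmonic 470.5 nm) and blue by band 20 (913.7 nm, second harmonic
#' 456.9 nm).  These indices are a property of the camera's band table.
#'
#' @return named integer vector `c(r, g, b)` of 1-based band indices.
#' @export
camera_prgb_bands <- function() c(r = 4L, g = 23L, b = 20L)

#' Construct a hyperspectral cube
#'
#' @param data numeric array `(bands, height, width)`, band-major.
#' @param wavelengths_nm ascending band-center wavelengths; length must
#'   equal the number of bands.
#' @param calibrated whether `data` holds reflectance (values `>= 0`)
#'   rather than raw sensor counts.
#' @export
hsi_cube <- function(data, wavelengths_nm = snapshot_wavelengths(),
                     calibrated = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] != length(wavelengths_nm))
    stop("band count must equal the number of wavelengths")
  if (is.unsorted(wavelengths_nm))
    stop("wavelengths must be ascending")
  if (calibrated && any(data < 0))
    stop("calibrated cubes must be non-negative")
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 calibrated = isTRUE(calibrated)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d bands x %d x %d, %s, %.1f-%.1f nm\n",
              d[1], d[2], d[3],
              if (x$calibrated) "reflectance" else "uncalibrated",
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Demosaic a snapshot-mosaic frame into a band cube
#'
#' The 25 spectral filters tile the sensor in a repeating 5x5 pattern; band
#' `b` (0-based, row-major within each tile, top-left = band 0) at cube
#' position `(i, j)` is the sensor pixel `(5 i + b %/% 5, 5 j + b %% 5)`.
#' Output spatial size is the frame size divided by 5.
#'
#' @param frame numeric matrix with both dimensions divisible by 5
#'   (the full sensor is 1085 x 2045, giving a 25 x 217 x 409 cube).
#' @param wavelengths_nm band-center wavelengths for the resulting cube.
#' @return an uncalibrated [hsi_cube()].
#' @export
demosaic <- function(frame, wavelengths_nm = snapshot_wavelengths()) {
  frame <- as.matrix(frame)
  h <- nrow(frame); w <- ncol(frame)
  if (h %% 5L != 0L || w %% 5L != 0L)
    stop("frame dimensions must be divisible by the 5x5 pattern size")
  oh <- h %/% 5L; ow <- w %/% 5L
  data <- array(0, c(25L, oh, ow))
  for (b in 0:24) {
    ri <- b %/% 5L; ci <- b %% 5L
    data[b + 1L, , ] <- frame[seq(ri + 1L, h, by = 5L),
                              seq(ci + 1L, w, by = 5L)]
  }
  hsi_cube(data, wavelengths_nm, calibrated = FALSE)
}

#' Inverse of [demosaic()]: re-tile a cube into a mosaic frame
#'
#' @param cube an [hsi_cube()] with 25 bands.
#' @return numeric matrix of size `(5 h, 5 w)`.
#' @export
mosaic_frame <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"), dim(cube$data)[1] == 25L)
  d <- dim(cube$data)
  frame <- matrix(0, 5L * d[2], 5L * d[3])
  for (b in 0:24) {
    ri <- b %/% 5L; ci <- b %% 5L
    frame[seq(ri + 1L, 5L * d[2], by = 5L),
          seq(ci + 1L, 5L * d[3], by = 5L)] <- cube$data[b + 1L, , ]
  }
  frame
}

#' White/dark reference pair
#'
#' @param white,dark [hsi_cube()]s with the same shape as the frames to
#'   calibrate; `white` must exceed `dark` on at least 99% of entries.
#' @export
reference_pair <- function(white, dark) {
  stopifnot(inherits(white, "hsi_cube"), inherits(dark, "hsi_cube"),
            all(dim(white$data) == dim(dark$data)))
  if (mean(white$data > dark$data) < 0.99)
    stop("white reference must exceed the dark reference almost everywhere")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Convert radiance counts to reflectance
#'
#' `(cube - dark) / (white - dark)` element-wise, with the divisor clamped
#' below by `eps` and the result clamped at 0.
#'
#' @param cube an uncalibrated [hsi_cube()].
#' @param ref a [reference_pair()] matching the cube's shape.
#' @param eps divisor clamp for degenerate reference pixels.
#' @return a calibrated [hsi_cube()].
#' @export
calibrate_reflectance <- function(cube, ref, eps = 1e-6) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(ref, "reference_pair"))
  if (!all(dim(cube$data) == dim(ref$white$data)))
    stop("cube and reference shapes differ")
  den <- pmax(ref$white$data - ref$dark$data, eps)
  out <- pmax((cube$data - ref$dark$data) / den, 0)
  hsi_cube(out, cube$wavelengths_nm, calibrated = TRUE)
}

#' Apply the sensor's spectral cross-talk correction matrix
#'
#' Replaces every pixel's 25-band spectrum `s` by `M s`.  The matrix is an
#' instrument input (provided by the sensor vendor); it is applied after
#' white/dark calibration.
#'
#' @param cube a calibrated [hsi_cube()].
#' @param scm 25x25 numeric matrix with finite entries.
#' @export
apply_spectral_correction <- function(cube, scm) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!cube$calibrated)
    stop("spectral correction applies to calibrated cubes only")
  scm <- as.matrix(scm)
  nb <- dim(cube$data)[1]
  if (!all(dim(scm) == c(nb, nb)) || !all(is.finite(scm)))
    stop("scm must be a finite square matrix matching the band count")
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = nb)        # bands x pixels
  out <- array(scm %*% flat, d)
  out <- structure(list(data = out, wavelengths_nm = cube$wavelengths_nm,
                        calibrated = TRUE), class = "hsi_cube")
  out
}

#' Second harmonic of a wavelength
#'
#' Half the wavelength, rounded half-up to 0.1 nm (940.9 nm -> 470.5 nm,
#' 913.7 nm -> 456.9 nm).
#'
#' @param wavelength_nm numeric wavelengths in nm.
#' @export
second_harmonic <- function(wavelength_nm) {
  floor(wavelength_nm / 2 * 10 + 0.5) / 10
}

# distance from a value to a closed interval (0 inside)
interval_dist <- function(x, range) pmax(range[1] - x, x - range[2], 0)

#' Select pseudo-RGB bands by harmonic wavelength matching
#'
#' Red is the first band at or beyond the red target (the camera only sees
#' red directly); green and blue are the bands whose second harmonics fall
#' nearest inside the visible green and blue ranges.  Bands are assigned
#' greedily (red, then green, then blue) without reuse; ties break toward
#' the longer wavelength.  For the physical camera the documented
#' assignment is [camera_prgb_bands()].
#'
#' @param wavelengths_nm ascending band-center wavelengths.
#' @param red_range,green_range,blue_range target visible ranges in nm.
#' @return named integer vector `c(r, g, b)` of 1-based band indices.
#' @export
select_rgb_bands_by_harmonic <- function(wavelengths_nm,
                                         red_range = c(700, 750),
                                         green_range = c(495, 570),
                                         blue_range = c(450, 495)) {
  if (is.unsorted(wavelengths_nm)) stop("wavelengths must be ascending")
  r_idx <- which(wavelengths_nm >= red_range[1])
  if (length(r_idx) == 0L)
    stop(sprintf("no band at or beyond the red target [%g, %g] nm",
                 red_range[1], red_range[2]))
  r <- r_idx[1]
  harm <- second_harmonic(wavelengths_nm)
  pick <- function(range, used) {
    cand <- setdiff(seq_along(wavelengths_nm), used)
    d <- interval_dist(harm[cand], range)
    best <- cand[d == min(d)]
    best[length(best)]  # ties toward longer wavelength
  }
  g <- pick(green_range, r)
  b <- pick(blue_range, c(r, g))
  if (interval_dist(harm[g], green_range) > 60 ||
      interval_dist(harm[b], blue_range) > 60)
    stop(sprintf(
      "no band with a second harmonic near green [%g, %g] / blue [%g, %g] nm",
      green_range[1], green_range[2], blue_range[1], blue_range[2]))
  c(r = r, g = g, b = b)
}

# per-channel histogram equalization via the empirical CDF
equalize_channel <- function(ch) {
  if (diff(range(ch)) < .Machine$double.eps) return(NULL)
  f <- ecdf(as.vector(ch))
  matrix(f(ch), nrow(ch), ncol(ch))
}

#' Reconstruct a pseudo-RGB image from a calibrated cube
#'
#' Selects the red/green/blue bands (by default the camera's documented
#' assignment), histogram-equalizes each channel independently, then
#' applies a global linear contrast stretch to the 1st-99th percentile.
#' Output values lie in `[0, 1]`; a constant band yields a flat 0.5
#' channel with a warning.
#'
#' @param cube a calibrated [hsi_cube()].
#' @param band_indices integer `(r, g, b)` band indices.
#' @export
reconstruct_prgb <- function(cube, band_indices = camera_prgb_bands()) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!cube$calibrated) stop("pseudo-RGB requires a calibrated cube")
  d <- dim(cube$data)
  img <- array(0.5, c(d[2], d[3], 3L))
  for (k in 1:3) {
    eq <- equalize_channel(cube$data[band_indices[k], , ])
    if (is.null(eq)) {
      warning(sprintf("band %d is constant; channel set to 0.5",
                      band_indices[k]))
    } else {
      img[, , k] <- eq
    }
  }
  qs <- quantile(img, c(0.01, 0.99), names = FALSE)
  if (qs[2] > qs[1]) img <- clamp((img - qs[1]) / (qs[2] - qs[1]), 0, 1)
  img
}

#' Fit per-band min-max normalization statistics
#'
#' Extracts the per-band minimum and maximum over the training and
#' validation cubes.
#'
#' @param cubes list of [hsi_cube()]s.
#' @return list with `xmin` and `xmax`, each of length = bands.
#' @export
fit_minmax <- function(cubes) {
  if (inherits(cubes, "hsi_cube")) cubes <- list(cubes)
  stopifnot(length(cubes) >= 1L)
  nb <- dim(cubes[[1]]$data)[1]
  xmin <- rep(Inf, nb); xmax <- rep(-Inf, nb)
  for (cb in cubes) {
    flat <- matrix(cb$data, nrow = nb)
    xmin <- pmin(xmin, apply(flat, 1, min))
    xmax <- pmax(xmax, apply(flat, 1, max))
  }
  list(xmin = xmin, xmax = xmax)
}

#' Apply min-max normalization to a cube
#'
#' Per-band affine map `(x - xmin) / (xmax - xmin)`.  Training pixels land
#' in `[0, 1]`; values outside the fitted range are not clipped.  Constant
#' bands (`xmax == xmin`) map to 0 with a warning.
#'
#' @param cube an [hsi_cube()].
#' @param stats output of [fit_minmax()].
#' @export
apply_minmax <- function(cube, stats) {
  stopifnot(inherits(cube, "hsi_cube"))
  nb <- dim(cube$data)[1]
  rng <- stats$xmax - stats$xmin
  if (any(rng < 0) || any(!is.finite(stats$xmin)) ||
      any(!is.finite(stats$xmax)))
    stop("invalid normalization statistics")
  out <- cube$data
  for (b in seq_len(nb)) {
    if (rng[b] == 0) {
      warning(sprintf("band %d has zero range; mapped to 0", b))
      out[b, , ] <- 0
    } else {
      out[b, , ] <- (cube$data[b, , ] - stats$xmin[b]) / rng[b]
    }
  }
  structure(list(data = out, wavelengths_nm = cube$wavelengths_nm,
                 calibrated = cube$calibrated), class = "hsi_cube")
}

#' Adapt a cube of arbitrary spatial size to the 217x409 network input
#'
#' Rotates 90 degrees if the height exceeds the width, downscales
#' (bilinear, aspect preserved) if the height still exceeds the target
#' height -- or by width if the scaled width would overflow -- and zero-pads
#' right/bottom to the target.  Returns the adapted cube plus a recipe that
#' [restore_spatial()] inverts.
#'
#' @param cube an [hsi_cube()].
#' @param target `(height, width)` of the network input.
#' @return list with `cube` and `recipe`.
#' @export
adapt_spatial <- function(cube, target = c(217L, 409L)) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  orig <- d[2:3]
  data <- cube$data
  rotated <- orig[1] > orig[2]
  if (rotated) {
    rot <- array(0, c(d[1], orig[2], orig[1]))
    for (b in seq_len(d[1]))
      rot[b, , ] <- t(data[b, , ])[, orig[1]:1]   # 90 deg clockwise
    data <- rot
  }
  cur <- dim(data)[2:3]
  scale <- 1
  if (cur[1] > target[1]) scale <- target[1] / cur[1]
  if (round(cur[2] * scale) > target[2]) {
    warning("scaling by width to fit the target frame")
    scale <- target[2] / cur[2]
  }
  scaled_dims <- cur
  if (scale < 1) {
    scaled_dims <- c(round(cur[1] * scale), round(cur[2] * scale))
    sc <- array(0, c(d[1], scaled_dims[1], scaled_dims[2]))
    for (b in seq_len(d[1]))
      sc[b, , ] <- resize_mat(data[b, , ], scaled_dims, "bilinear")
    data <- sc
  }
  out <- array(0, c(d[1], target[1], target[2]))
  out[, seq_len(scaled_dims[1]), seq_len(scaled_dims[2])] <- data
  recipe <- list(rotated = rotated, scale = scale,
                 scaled_dims = scaled_dims,
                 pre_scale_dims = cur, orig_dims = orig, target = target)
  list(cube = structure(list(data = out,
                             wavelengths_nm = cube$wavelengths_nm,
                             calibrated = cube$calibrated),
                        class = "hsi_cube"),
       recipe = recipe)
}

#' Restore a mask predicted at network resolution to the original frame
#'
#' Inverts [adapt_spatial()]: crops the zero padding, upscales
#' (nearest-neighbour) to the pre-scaling size, and rotates back.
#' Pad-only recipes restore values bit-exactly.
#'
#' @param mask numeric matrix at the adapted (target) resolution.
#' @param recipe the recipe returned by [adapt_spatial()].
#' @export
restore_spatial <- function(mask, recipe) {
  m <- as.matrix(mask)
  stopifnot(all(dim(m) == recipe$target))
  m <- m[seq_len(recipe$scaled_dims[1]), seq_len(recipe$scaled_dims[2]),
         drop = FALSE]
  if (recipe$scale < 1) m <- resize_mat(m, recipe$pre_scale_dims, "nearest")
  if (recipe$rotated) m <- t(m[, ncol(m):1, drop = FALSE])[, , drop = FALSE]
  m
}
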