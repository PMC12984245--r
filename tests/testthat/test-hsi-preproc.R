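test_that("demosaicking follows the 5x5 mosaic geometry", {
  # full sensor frame -> 25 x 217 x 409 cube
  frame <- matrix(runif(1085 * 2045), 1085, 2045)
  cube <- demosaic(frame)
  expect_equal(dim(cube$data), c(25L, 217L, 409L))
  expect_false(cube$calibrated)
  # a single 5x5 tile with values 0..24 row-major: band b is the pixel b
  tile <- matrix(0:24, 5, 5, byrow = TRUE)
  ct <- demosaic(tile)
  expect_equal(as.vector(ct$data), 0:24)
  # round trip is bit-exact
  expect_identical(mosaic_frame(cube), frame)
  expect_error(demosaic(matrix(0, 7, 10)), "divisible")
})

test_that("reflectance calibration follows (x - dark) / (white - dark)", {
  sc <- test_scene(1)
  ref <- reference_pair(sc$white, sc$dark)
  w_cal <- calibrate_reflectance(sc$white, ref)
  expect_equal(max(abs(w_cal$data - 1)), 0, tolerance = 1e-12)
  d_cal <- calibrate_reflectance(sc$dark, ref)
  expect_equal(max(abs(d_cal$data)), 0, tolerance = 1e-12)
  mid <- hsi_cube((sc$white$data + sc$dark$data) / 2, calibrated = FALSE)
  m_cal <- calibrate_reflectance(mid, ref)
  expect_equal(max(abs(m_cal$data - 0.5)), 0, tolerance = 1e-12)
  expect_true(w_cal$calibrated)
  small <- hsi_cube(array(0.5, c(25, 2, 2)), calibrated = FALSE)
  expect_error(calibrate_reflectance(small, ref), "shapes")
})

test_that("calibration is affine per pixel in the reference frame", {
  sc <- test_scene(1)
  ref <- reference_pair(sc$white, sc$dark)
  a <- 0.3; b <- 0.45
  mix <- hsi_cube(a * sc$cube$data * (sc$white$data - sc$dark$data) +
                    b * sc$white$data + (1 - b) * sc$dark$data,
                  calibrated = FALSE)
  got <- calibrate_reflectance(mix, ref)
  expect_equal(got$data, a * sc$cube$data + b, tolerance = 1e-10)
})

test_that("spectral correction multiplies every pixel spectrum", {
  px <- hsi_cube(array(runif(25), c(25, 1, 1)), calibrated = TRUE)
  scm <- matrix(rnorm(625), 25, 25)
  got <- apply_spectral_correction(px, scm)
  expect_equal(as.vector(got$data), as.vector(scm %*% px$data[, 1, 1]),
               tolerance = 1e-12)
  cube <- hsi_cube(array(runif(25 * 4 * 3), c(25, 4, 3)), calibrated = TRUE)
  expect_equal(apply_spectral_correction(cube, diag(25))$data, cube$data)
  expect_equal(apply_spectral_correction(cube, 2 * diag(25))$data,
               2 * cube$data)
  raw <- hsi_cube(cube$data, calibrated = FALSE)
  expect_error(apply_spectral_correction(raw, diag(25)), "calibrated")
})

test_that("second harmonics match the documented camera arithmetic", {
  expect_equal(second_harmonic(940.9), 470.5)
  expect_equal(second_harmonic(913.7), 456.9)
  wl <- snapshot_wavelengths()
  expect_length(wl, 25)
  expect_false(is.unsorted(wl))
  expect_equal(wl[4], 712.4)
  expect_equal(wl[20], 913.7)
  expect_equal(wl[23], 940.9)
  expect_equal(unname(camera_prgb_bands()), c(4L, 23L, 20L))
})

test_that("harmonic band selection picks red directly and green/blue by halves", {
  # constructed table where the arithmetic is unambiguous: band 2 is the
  # first at/beyond the red target; bands 4 and 3 have harmonics inside
  # the green and blue ranges
  wl <- c(680, 705, 930, 1060, 1500)
  sel <- select_rgb_bands_by_harmonic(wl)
  expect_equal(unname(sel), c(2L, 4L, 3L))   # 1060/2 = 530, 930/2 = 465
  expect_error(select_rgb_bands_by_harmonic(c(400, 450, 500)), "red")
  expect_error(select_rgb_bands_by_harmonic(c(700, 701, 702)), "harmonic")
})

test_that("pseudo-RGB reconstruction equalizes and stays in [0, 1]", {
  sc <- test_scene(1)
  img <- reconstruct_prgb(sc$cube)
  expect_equal(dim(img), c(217L, 409L, 3L))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  # vessels darker than cortex in the red channel
  expect_lt(mean(img[, , 1][sc$vessel_truth == 1L]),
            mean(img[, , 1][sc$class_map == 1L]))
  flat <- hsi_cube(array(0.5, c(25, 8, 8)), calibrated = TRUE)
  w <- capture_warnings(img2 <- reconstruct_prgb(flat))
  expect_length(w, 3)                      # one per constant channel
  expect_true(all(grepl("constant", w)))
  expect_true(all(img2 == 0.5))
})

test_that("min-max normalization lands training pixels in [0, 1]", {
  sc <- test_scene(1)
  stats <- fit_minmax(list(sc$cube))
  norm <- apply_minmax(sc$cube, stats)
  for (b in c(1, 13, 25)) {
    expect_equal(min(norm$data[b, , ]), 0, tolerance = 1e-12)
    expect_equal(max(norm$data[b, , ]), 1, tolerance = 1e-12)
  }
  # interior point arithmetic
  x <- stats$xmin[1] + 0.25 * (stats$xmax[1] - stats$xmin[1])
  probe <- sc$cube
  probe$data[1, 1, 1] <- x
  expect_equal(apply_minmax(probe, stats)$data[1, 1, 1], 0.25,
               tolerance = 1e-12)
  # constant band maps to zero with a warning
  cdata <- array(runif(25 * 4), c(25, 2, 2))
  cdata[1, , ] <- 0.7
  const <- hsi_cube(cdata, calibrated = TRUE)
  cs <- fit_minmax(list(const))
  expect_warning(cn <- apply_minmax(const, cs), "zero range")
  expect_true(all(cn$data[1, , ] == 0))
  # test pixels outside the fitted range are not clipped
  probe$data[1, 1, 1] <- stats$xmax[1] + 1
  expect_gt(max(apply_minmax(probe, stats)$data[1, , ]), 1)
})

test_that("spatial adaptation rotates, scales, pads and restores", {
  mk <- function(h, w) hsi_cube(array(runif(25 * h * w), c(25, h, w)),
                                calibrated = TRUE)
  # identity
  a1 <- adapt_spatial(mk(217, 409))
  expect_false(a1$recipe$rotated)
  expect_equal(a1$recipe$scale, 1)
  # rotation only
  a2 <- adapt_spatial(mk(409, 217))
  expect_true(a2$recipe$rotated)
  expect_equal(a2$recipe$scale, 1)
  expect_equal(dim(a2$cube$data), c(25L, 217L, 409L))
  # scale + pad: 434 x 600 -> 217 x 300 -> padded 217 x 409
  a3 <- adapt_spatial(mk(434, 600))
  expect_equal(a3$recipe$scaled_dims, c(217, 300))
  expect_equal(dim(a3$cube$data), c(25L, 217L, 409L))
  expect_true(all(a3$cube$data[, , 301:409] == 0))
  mask <- matrix(runif(217 * 409) > 0.5, 217, 409) * 1
  expect_equal(dim(restore_spatial(mask, a3$recipe)), c(434L, 600L))
  # pad-only recipes restore bit-exactly
  a4 <- adapt_spatial(mk(100, 200))
  m4 <- matrix(0, 217, 409); m4[1:100, 1:200] <- matrix(runif(20000), 100)
  expect_identical(restore_spatial(m4, a4$recipe), m4[1:100, 1:200])
  # rotation restores orientation exactly
  src <- matrix(runif(409 * 217), 409, 217)
  a5 <- adapt_spatial(hsi_cube(array(rep(src, each = 25), c(25, 409, 217)),
                               calibrated = TRUE))
  expect_equal(restore_spatial(a5$cube$data[1, , ], a5$recipe), src)
})
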