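test_that("patch masks are unions of rectangles", {
  ann <- structure(list(
    positive_patches = data.frame(top = c(5L, 5L, 30L),
                                  left = c(5L, 10L, 30L),
                                  size = c(10L, 10L, 10L)),
    image_size = c(50L, 60L)), class = "patch_annotation_set")
  m <- build_patch_mask(ann)
  # overlapping pair: brute-force union area
  brute <- matrix(0L, 50, 60)
  brute[5:14, 5:14] <- 1L; brute[5:14, 10:19] <- 1L; brute[30:39, 30:39] <- 1L
  expect_identical(m, cortexfuse:::as_mask(brute))
  one <- ann; one$positive_patches <- one$positive_patches[1, ]
  expect_equal(sum(build_patch_mask(one)), 100)
  bad <- ann; bad$positive_patches$top[1] <- 45L
  expect_error(build_patch_mask(bad), "bounds")
  empty <- ann; empty$positive_patches <- NULL
  expect_error(build_patch_mask(empty), "empty")
})

test_that("negative patches respect the Chebyshev safety margin", {
  # default margin is half the HSI frame height
  expect_equal(formals(sample_negative_patches)$margin, 108L)
  expect_equal(floor(217 / 2), 108)
  mask <- matrix(0L, 900, 900)
  mask[400:500, 400:500] <- 1L
  pat <- sample_negative_patches(mask, patch_size = 100L, margin = 50L,
                                 seed = 3)
  expect_gt(nrow(pat), 0)
  # verify margin by distance transform and mutual non-overlap
  occupancy <- matrix(0L, 900, 900)
  for (i in seq_len(nrow(pat))) {
    rows <- pat$top[i]:(pat$top[i] + 99L)
    cols <- pat$left[i]:(pat$left[i] + 99L)
    # Chebyshev distance of every patch pixel to the mask
    dr <- pmax(400 - rows, rows - 500, 0)
    dc <- pmax(400 - cols, cols - 500, 0)
    expect_gte(min(pmax(outer(dr, dc, pmax))), 50)
    occupancy[rows, cols] <- occupancy[rows, cols] + 1L
  }
  expect_lte(max(occupancy), 1L)
  # determinism
  expect_identical(pat, sample_negative_patches(mask, 100L, 50L, seed = 3))
  # no room -> empty with warning
  full <- matrix(1L, 300, 300)
  full[1:10, 1:10] <- 0L
  expect_warning(none <- sample_negative_patches(full, 100L, 50L, seed = 1),
                 "no valid")
  expect_equal(nrow(none), 0)
})

test_that("cortex refinement improves on the raw patch annotation", {
  sc <- test_scene(1)
  ann <- generate_patch_annotations(sc, seed = 4)
  pm <- build_patch_mask(ann)
  refined <- refine_cortex_annotation(sc$rgb, pm, seed = 1)
  # monotone growth: contains the closing of the patch mask
  closed <- cortexfuse:::mask_close(pm, 3)
  expect_true(all(refined[closed == 1L] == 1L))
  expect_gt(dsc(refined, sc$rgb_cortex_gold), dsc(pm, sc$rgb_cortex_gold))
  expect_error(refine_cortex_annotation(sc$rgb, pm, k_clusters = 1L), "2")
  expect_error(refine_cortex_annotation(sc$rgb, pm * 0L), "empty")
})

test_that("refinement saturates on a uniform-color image", {
  withr::with_seed(2, {
    img <- array(0.5 + rnorm(80 * 120 * 3, 0, 0.005), c(80, 120, 3))
  })
  pm <- matrix(0L, 80, 120); pm[30:50, 40:70] <- 1L
  refined <- suppressWarnings(
    refine_cortex_annotation(img, pm, k_clusters = 4L, seed = 1))
  # no vessel-like clusters to propagate through: stays at the closed mask
  expect_equal(refined, cortexfuse:::mask_close(pm, 3), ignore_attr = TRUE)
})

test_that("perimeter approximation traces the true cortex boundary", {
  sc <- test_scene(1)
  refined <- sc$rgb_cortex_gold
  contour <- approximate_perimeter(sc$rgb, refined)
  expect_gt(sum(contour), 100)
  d <- cortexfuse:::dist_to_set(cortexfuse:::boundary_4(sc$rgb_cortex_gold))
  expect_lt(mean(d[contour == 1L]), 3)
  # edge-free image -> empty contour
  flat <- array(0.5, c(60, 80, 3))
  m <- matrix(0L, 60, 80); m[20:40, 30:60] <- 1L
  expect_equal(sum(approximate_perimeter(flat, m)), 0)
  # mask touching the border must not error
  mb <- matrix(0L, 60, 80); mb[1:30, 1:40] <- 1L
  expect_silent(approximate_perimeter(sc$rgb[1:60, 1:80, ], mb))
  expect_error(approximate_perimeter(sc$rgb, refined * 0L), "empty")
})

test_that("operator bank geometry: angular step, zero mean, symmetry", {
  bank <- make_operator_bank(k_thin = 7L, k_thick = 15L, n = 12L)
  expect_equal(180 / bank$n_orientations, 15)  # 15-degree offsets
  for (size in c("thin", "thick"))
    for (ker in bank$kernels[[size]]) {
      expect_lt(abs(sum(ker)), 1e-12)
      # a line through the center is symmetric under 180-degree rotation
      expect_equal(ker, ker[rev(seq_len(nrow(ker))), rev(seq_len(ncol(ker)))])
    }
  # horizontal kernel: center row positive
  k0 <- bank$kernels$thin[[1]]
  expect_true(all(k0[4, ] > 0))
  expect_error(make_operator_bank(k_thin = 6L), "odd")
})

test_that("line operators respond maximally at the line orientation", {
  # dark straight line at 30 degrees on a bright background
  h <- 41; w <- 41
  img <- matrix(1, h, w)
  th <- 30 * pi / 180
  for (t in seq(-19, 19, by = 0.25)) {
    r <- round(21 + t * sin(th)); c <- round(21 + t * cos(th))
    if (r >= 1 && r <= h && c >= 1 && c <= w) img[r, c] <- 0
  }
  bank <- make_operator_bank(k_thin = 7L, k_thick = 15L)
  inv <- 1 - img
  # brute-force correlation at the center pixel for each orientation
  resp <- vapply(seq_len(12), function(i) {
    ker <- bank$kernels$thick[[i]]
    sum(inv[14:28, 14:28] * ker)
  }, numeric(1))
  expect_equal(which.max(resp), 3L)  # orientations 0, 15, 30, ...
  # detection works; bright lines (inverted contrast) do not fire
  mask <- detect_vessels(img, bank, threshold_quantile = 0.95, min_area = 5L)
  expect_gt(sum(mask * (1 - img > 0)), 0)
  maskb <- detect_vessels(1 - img, bank, threshold_quantile = 0.95,
                          min_area = 5L)
  expect_lt(sum(maskb[img == 0]), sum(mask[img == 0]))
  # constant image -> empty mask
  expect_equal(sum(detect_vessels(matrix(0.5, 30, 30), bank)), 0)
})

test_that("ground-truth densification bridges and never removes labels", {
  # two same-class blobs 5 px apart are bridged by the 11x11 closing
  toy <- matrix(0L, 30, 30)
  toy[14:16, 5:10] <- 1L
  toy[14:16, 16:21] <- 1L
  dens <- densify_gt(toy)
  expect_gt(sum(dens[14:16, 11:15] == 1L), 0)         # gap bridged
  expect_equal(max(EBImage::bwlabel(dens == 1L)), 1)  # now one component
  # isolated pixel survives (closing is extensive on its input)
  iso <- matrix(0L, 30, 30); iso[15, 15] <- 2L
  expect_equal(densify_gt(iso)[15, 15], 2L)
  # blobs of different classes 2 px apart: contested zone unlabeled
  mix <- matrix(0L, 30, 30)
  mix[14:16, 5:12] <- 1L
  mix[14:16, 15:22] <- 2L
  dmix <- densify_gt(mix)
  expect_true(all(dmix[15, 13:14] == 0L))
  # inputs preserved, no invented classes
  expect_true(all(dmix[mix == 1L] == 1L))
  expect_true(all(dmix[mix == 2L] == 2L))
  expect_equal(sum(densify_gt(toy) == 3L), 0L)
})

test_that("background complementation avoids the cortex", {
  sc <- test_scene(1)
  dens <- densify_gt(sc$gt_sparse)
  bg <- complement_background(sc$cube, dens, seed = 1)
  overlap <- sum(bg * sc$cortex_gold) / max(sum(bg), 1)
  expect_lt(overlap, 0.05)
  expect_equal(sum(complement_background(sc$cube, dens, n_background = 0L)),
               0)
  expect_error(complement_background(sc$cube, dens, k_clusters = 4L,
                                     n_background = 8L), "exceed")
})

test_that("adjusted ground truth separates inner, outer and unknown", {
  sc <- test_scene(1)
  dens <- densify_gt(sc$gt_sparse)
  bg <- complement_background(sc$cube, dens, seed = 1)
  adj <- build_adjusted_gt(dens, bg)
  expect_setequal(unique(as.vector(adj)), c(0L, 1L, 2L))
  # inner and outer are disjoint by construction; inner covers the
  # cortical labels and takes precedence over dura inside the hull
  cortical <- dens %in% 1:3
  expect_true(all(adj[cortical] == 1L))
  # inner stays close to the true cortex
  dil <- cortexfuse:::mask_dilate(sc$cortex_gold, 10)
  expect_gt(mean(dil[adj == 1L]), 0.95)
  # convex cluster: inner contains its convex hull interior
  toy <- matrix(0L, 40, 40)
  toy[c(10, 30), c(10, 30)] <- 1L  # four corner points
  toy[20, 20] <- 2L
  adj2 <- build_adjusted_gt(toy, matrix(0L, 40, 40))
  expect_true(all(adj2[15:25, 15:25] == 1L))
  expect_error(build_adjusted_gt(matrix(0L, 10, 10), matrix(0L, 10, 10)),
               "cortical")
})

test_that("RGB adaptation crops to the target mask fraction and size", {
  sc <- test_scene(1)
  refined <- sc$rgb_cortex_gold
  ad <- adapt_rgb_dataset(sc$rgb, refined,
                          masks = list(refined = refined))
  expect_equal(dim(ad$image), c(217L, 409L, 3L))
  expect_equal(dim(ad$masks$refined), c(217L, 409L))
  expect_gte(min(ad$image), 0)
  expect_lte(max(ad$image), 1)
  # window area ~ mask area / fraction (unless clipped by the frame)
  win_area <- ad$window["height"] * ad$window["width"]
  expected <- sum(refined) / 0.20
  if (win_area < nrow(sc$rgb) * ncol(sc$rgb))
    expect_equal(unname(win_area), expected, tolerance = 0.15)
  # aspect ratio preserved
  expect_equal(unname(ad$window["width"] / ad$window["height"]), 409 / 217,
               tolerance = 0.05)
  # mask at a corner: window shifted, still inside the frame
  corner <- matrix(0L, 270, 480); corner[1:40, 1:40] <- 1L
  ad2 <- adapt_rgb_dataset(sc$rgb, corner)
  expect_gte(ad2$window["top"], 1)
  expect_gte(ad2$window["left"], 1)
})

test_that("vessel detection is approximately rotation-consistent", {
  sc <- test_scene(1)
  g <- sc$cube$data[4, , ]
  g <- (g - min(g)) / diff(range(g))
  bank <- make_operator_bank(k_thin = 5L, k_thick = 11L)
  m1 <- detect_vessels(g, bank, min_area = 10L)
  g_rot <- t(g)[ncol(g):1, ]                      # rotate 90 deg
  m2r <- detect_vessels(g_rot, bank, min_area = 10L)
  m2 <- t(m2r[nrow(m2r):1, ])                     # rotate back
  expect_lt(mean(m1 != m2), 0.02)
})
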