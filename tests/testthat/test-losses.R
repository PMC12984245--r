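test_that("concave hull fill encloses blobs and bridges split masks", {
  d1 <- disc_mask(60, 60, 30, 30, 15)
  h1 <- hull_fill(d1)
  expect_gte(dsc(h1, d1), 99)            # convex solid: hull ~ itself
  # two distant blobs: the hull bridges the gap (a tight concave bridge)
  two <- disc_mask(60, 90, 30, 20, 10) | disc_mask(60, 90, 30, 70, 10)
  h2 <- hull_fill(two)
  expect_gt(sum(h2), sum(two))
  expect_true(all(h2[two == 1]))
  lab <- cortexfuse:::mask_label(h2, 4L)
  expect_equal(max(lab), 1L)        # bridged into one component
  # a C-shape gets a tighter hull than its convex hull
  cshape <- disc_mask(80, 80, 40, 40, 30) - disc_mask(80, 80, 40, 40, 18)
  cshape[30:50, 40:80] <- 0
  ch <- grDevices::chull(which(cshape == 1, arr.ind = TRUE)[, 2:1])
  hc <- hull_fill(cshape, concavity = 2)
  convex_area <- sum(hull_fill(cortexfuse:::as_mask(
    disc_mask(80, 80, 40, 40, 30))))
  expect_lt(sum(hc), convex_area)
  expect_equal(sum(hull_fill(matrix(0L, 10, 10))), 0)
})

test_that("DSC+BCE loss matches hand arithmetic on a 2x2 toy", {
  pred <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)   # rows (.9,.1), (.8,.2)
  target <- matrix(c(1, 1, 0, 0), 2, 2)
  # by hand: soft dice = (2(0.9+0.8)+1)/((0.9+0.1+0.8+0.2)+2+1)
  sdice <- (2 * 1.7 + 1) / (2 + 2 + 1)
  bce <- -(log(0.9) + log(0.8) + log(1 - 0.1) + log(1 - 0.2)) / 4
  expect_equal(dsc_bce_loss(pred, target), (1 - sdice) + bce,
               tolerance = 1e-12)
  # perfect / inverted predictions
  hard <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(dsc_bce_loss(cortexfuse:::clamp(hard, 1e-6, 1 - 1e-6), hard),
            1e-4)
  inv <- cortexfuse:::clamp(1 - hard, 1e-6, 1 - 1e-6)
  expect_gt(dsc_bce_loss(inv, hard), 1)
  expect_error(dsc_bce_loss(pred, matrix(0, 3, 3)), "shapes")
})

test_that("excess loss follows log(alpha DSC + 1) with landmark values", {
  y <- matrix(0, 64, 64); y[16:48, 16:48] <- 1  # refined annotation
  nested <- matrix(0, 64, 64); nested[24:40, 24:40] <- 1  # inside y
  expect_lt(excess_loss(nested, y), 5e-3)
  comp <- 1 - y
  expect_equal(excess_loss(comp, y), log(11), tolerance = 5e-3)
  expect_equal(log(11), 2.3979, tolerance = 1e-4)
  # batch of the two -> mean
  batch_p <- array(c(nested, comp), c(64, 64, 2))
  batch_y <- array(c(y, y), c(64, 64, 2))
  expect_equal(excess_loss(batch_p, batch_y),
               (excess_loss(nested, y) + excess_loss(comp, y)) / 2,
               tolerance = 1e-12)
  expect_error(excess_loss(nested, matrix(0, 10, 10)), "differ")
})

test_that("excess loss grows monotonically as the mask leaks outside", {
  y <- matrix(0, 60, 60); y[20:40, 20:40] <- 1
  prev <- -Inf
  for (r in c(0, 4, 8, 12)) {
    pred <- cortexfuse:::mask_dilate(y, r) * 1
    cur <- excess_loss(pred, y)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("self-hull loss prefers solid masks over fragmented ones", {
  solid <- disc_mask(60, 60, 30, 30, 15)
  expect_lt(self_hull_loss(cortexfuse:::clamp(solid, 0.001, 0.999)), 0.02)
  split <- disc_mask(60, 90, 30, 15, 10) | disc_mask(60, 90, 30, 75, 10)
  l_split <- self_hull_loss(cortexfuse:::clamp(split * 1, 0.001, 0.999))
  expect_gt(l_split, 0.05)
  expect_gt(l_split,
            self_hull_loss(cortexfuse:::clamp(solid, 0.001, 0.999)))
  expect_equal(self_hull_loss(matrix(0, 20, 20)), 1)
})

test_that("cross-hull loss measures hull overlap with disc arithmetic", {
  expect_lt(cross_hull_loss(disc_mask(60, 60, 30, 30, 20) + 0,
                            disc_mask(60, 60, 30, 30, 20) + 0), 0.02)
  # concentric discs, radius halved: Dice = 2(1/4)/(1+1/4) = 0.4
  big <- disc_mask(80, 80, 40, 40, 24) + 0
  small <- disc_mask(80, 80, 40, 40, 12) + 0
  # oracle from the actual rasterized hull regions
  oracle <- 1 - 2 * sum(big * small) / (sum(big) + sum(small))
  got <- cross_hull_loss(big, small)
  expect_equal(got, oracle, tolerance = 0.05)
  expect_equal(got, 0.6, tolerance = 0.05)
  expect_equal(cross_hull_loss(big, matrix(0, 80, 80)), 1)
})

test_that("contour loss rewards aligned boundaries", {
  solid <- disc_mask(60, 60, 30, 30, 15)
  pred <- cortexfuse:::clamp(solid, 0.001, 0.999)
  edge <- cortexfuse:::pred_edge_indicator(pred)
  aligned <- contour_loss(pred, edge)
  expect_lt(aligned, 0.05)
  shifted <- disc_mask(60, 60, 30, 30, 15)
  off <- cortexfuse:::pred_edge_indicator(
    cortexfuse:::clamp(disc_mask(60, 60, 30, 40, 15), 0.001, 0.999))
  expect_gt(contour_loss(pred, off), aligned)
  expect_equal(contour_loss(pred, matrix(0L, 60, 60)), 0)
})

test_that("total RGB loss is the exact sum of its components", {
  sc <- test_scene(1)
  ad <- adapt_rgb_dataset(sc$rgb, sc$rgb_cortex_gold,
                          masks = list(refined = sc$rgb_cortex_gold,
                                       vessel = sc$rgb_vessel_truth))
  refined <- ad$masks$refined
  vessel <- ad$masks$vessel
  contour <- cortexfuse:::pred_edge_indicator(
    cortexfuse:::clamp(refined, 0.001, 0.999))
  outputs <- list(cortex_prob = cortexfuse:::clamp(refined, 1e-3, 1 - 1e-3),
                  vessel_prob = cortexfuse:::clamp(vessel, 1e-3, 1 - 1e-3))
  pl <- list(refined = refined, contour = contour, vessel = vessel)
  comps <- total_rgb_loss(outputs, pl)
  expect_equal(comps$total,
               comps$l_ctx + comps$l_self_hull + comps$l_cont +
                 comps$l_vsl + comps$l_cross_hull + comps$l_excess,
               tolerance = 1e-12)
  # the direct segmentation terms vanish for near-perfect predictions;
  # the cross-hull term reflects how far the vessel hull is from
  # spanning the cortex and need not vanish on these scenes
  expect_lt(comps$l_ctx, 0.1)
  expect_lt(comps$l_vsl, 0.15)
  expect_lt(comps$l_excess, 0.05)
  expect_true(all(unlist(comps) >= 0))
  expect_error(total_rgb_loss(outputs, pl[c("refined", "contour")]),
               "vessel")
})

test_that("supervised contrastive loss matches a brute-force evaluation", {
  # two identical same-class embeddings, two orthogonal other-class
  z <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  labels <- c(1, 1, 2, 2)
  tau <- 0.1
  # independent brute-force sum over anchor/positive pairs
  brute <- 0; n_anchor <- 0
  for (i in 1:4) {
    pos <- setdiff(which(labels == labels[i]), i)
    if (length(pos) == 0) next
    n_anchor <- n_anchor + 1
    li <- 0
    for (p in pos) {
      den <- sum(exp(colSums(z[, -i, drop = FALSE] * z[, i]) / tau))
      li <- li - log(exp(sum(z[, i] * z[, p]) / tau) / den)
    }
    brute <- brute + li / length(pos)
  }
  brute <- brute / n_anchor
  expect_equal(supcon_loss(z, labels, tau), brute, tolerance = 1e-10)
  # orthogonal class structure beats shuffled labels
  expect_lt(supcon_loss(z, labels, tau), supcon_loss(z, c(1, 2, 1, 2), tau))
  # temperature sweep is monotone for this separable geometry
  vals <- vapply(c(0.05, 0.1, 0.2, 0.5), function(tt)
    supcon_loss(z, labels, tt), numeric(1))
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  expect_error(supcon_loss(z, c(1, 2, 3, 4)), "positive")
})

test_that("masked BCE terms use inner/outer and ignore unknown exactly", {
  adj <- matrix(0L, 5, 5)
  adj[1, 1:3] <- 1L  # 3 inner
  adj[2, 1:2] <- 2L  # 2 outer
  pred <- matrix(0.5, 5, 5)
  pred[1, 1:3] <- 0.8
  pred[2, 1:2] <- 0.3
  hand <- mean(c(rep(-log(0.8), 3), rep(-log(0.7), 2)))
  expect_equal(masked_cortex_bce(pred, adj), hand, tolerance = 1e-12)
  # unknown-only changes leave the loss untouched
  pred2 <- pred; pred2[4, 4] <- 0.99
  expect_equal(masked_cortex_bce(pred2, adj), masked_cortex_bce(pred, adj))
  expect_warning(z <- masked_cortex_bce(pred, matrix(0L, 5, 5)), "unknown")
  expect_equal(z, 0)

  vp <- matrix(0L, 5, 5); vp[1, 1] <- 1L; vp[3, 3] <- 1L  # one outside inner
  pv <- matrix(1e-6, 5, 5)
  pv[1, 1] <- 0.9          # matches the pseudo-label on inner
  l1 <- masked_vessel_bce(pv, vp, adj)
  # pseudo-label outside inner is ignored entirely
  vp2 <- vp; vp2[3, 3] <- 0L
  expect_equal(masked_vessel_bce(pv, vp2, adj), l1)
  # activation on an outer pixel contributes -log(1 - p)
  pv2 <- pv; pv2[2, 1] <- 0.9
  expect_equal(masked_vessel_bce(pv2, vp, adj) - l1, -log(0.1) / 5,
               tolerance = 1e-6)
})

test_that("all losses are finite and non-negative on clamped inputs", {
  withr::with_seed(9, {
    for (i in 1:5) {
      p <- cortexfuse:::clamp(matrix(runif(400), 20, 20), 1e-6, 1 - 1e-6)
      q <- cortexfuse:::clamp(matrix(runif(400), 20, 20), 1e-6, 1 - 1e-6)
      t1 <- random_mask(20, 20, 0.4)
      vals <- c(dsc_bce_loss(p, t1), excess_loss(p, t1),
                self_hull_loss(p), cross_hull_loss(p, q),
                contour_loss(p, t1))
      expect_true(all(is.finite(vals)))
      expect_true(all(vals >= 0))
    }
  })
})

test_that("equivariance loss vanishes for identity and flip-invariant nets", {
  model <- build_cortexnet(network_config(base_channels = 4L,
                                          stage_blocks = c(1L, 1L, 1L)),
                           seed = 1)
  x <- array(runif(24 * 32 * 3), c(24, 32, 3, 1))
  l_id <- equivariance_loss(model, x, "rgb", transform_set = "identity",
                            training = FALSE)
  expect_equal(cortexfuse:::agt_value(l_id), 0, tolerance = 1e-12)
  # flips on a flip-symmetric input: a constant image is flip-invariant,
  # and so is the prediction of any convolutional net on it (up to
  # padding asymmetries at the border, which cancel under flip pairs)
  l_fl <- cortexfuse:::agt_value(
    equivariance_loss(model, x, "rgb", transform_set = "hflip",
                      training = FALSE, seed = 1))
  expect_true(is.finite(l_fl) && l_fl >= 0)
})
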