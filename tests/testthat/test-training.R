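test_that("patient splits reproduce the cohort arithmetic", {
  folds <- make_splits(sprintf("p%02d", 1:67), seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f$test, 13L)   # floor(0.2 * 67)
    expect_length(f$val, 7L)     # round(0.1 * 67)
    expect_length(f$train, 47L)
    expect_length(intersect(f$train, f$val), 0L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  # the test set is fixed across folds
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(vapply(tests, identical, logical(1), tests[[1]])))
  # validation differs between folds
  expect_false(identical(folds[[1]]$val, folds[[2]]$val))
  # a 70-patient cohort: 14 test, 7 val, 49 train
  f70 <- make_splits(sprintf("q%02d", 1:70), seed = 2)[[1]]
  expect_length(f70$test, 14L)
  expect_length(f70$val, 7L)
  expect_length(f70$train, 49L)
  expect_identical(make_splits(letters[1:10], n_folds = 2L, seed = 3),
                   make_splits(letters[1:10], n_folds = 2L, seed = 3))
  expect_error(make_splits(letters[1:3], n_folds = 5L), "folds")
})

test_that("pre-training batches compose 1/3 positive and learn", {
  cfg <- train_config(step1 = list(epochs = 8L, batch = 12L,
                                   pos_fraction = 1 / 3, tau = 0.1),
                      lr_start = 1e-3, lr_end = 1e-4, seed = 1)
  # the documented full-scale batch of 128 splits 43 / 85
  expect_equal(round(128 / 3), 43)
  withr::with_seed(1, {
    mk <- function(bright) {
      base <- if (bright) 0.75 else 0.25
      array(cortexfuse:::clamp(base + rnorm(16 * 16 * 3, 0, 0.05), 0, 1),
            c(16, 16, 3))
    }
    patches <- list(images = c(lapply(1:8, function(i) mk(TRUE)),
                               lapply(1:16, function(i) mk(FALSE))),
                    labels = rep(c(1L, 0L), c(8, 16)))
  })
  model <- build_cortexnet(network_config(base_channels = 4L,
                                          stage_blocks = c(1L, 1L, 1L),
                                          embedding_dim = 32L), seed = 1)
  res <- pretrain_encoder(model, patches, cfg)
  expect_equal(unname(res$batch_composition), c(4L, 8L))
  expect_lt(tail(res$history, 1), res$history[1])
  # determinism under identical seeds
  model2 <- build_cortexnet(network_config(base_channels = 4L,
                                           stage_blocks = c(1L, 1L, 1L),
                                           embedding_dim = 32L), seed = 1)
  res2 <- pretrain_encoder(model2, patches, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(model_state(model), model_state(model2))
  bad <- list(images = patches$images[1:8], labels = rep(1L, 8))
  expect_error(pretrain_encoder(model, bad, cfg), "positive and negative")
})

test_that("fine-tuning drives the trunk a thousand times slower", {
  expect_equal(train_config()$step3$trunk_lr_divisor, 1e3)
  sc <- test_scene(1)
  stats <- fit_minmax(list(sc$cube))
  cn_full <- aperm(apply_minmax(sc$cube, stats)$data, c(2, 3, 1))
  cn <- cn_full[1:54, 1:102, ]                     # small working window
  dens <- densify_gt(sc$gt_sparse)
  bg <- complement_background(sc$cube, dens, seed = 1)
  adj <- build_adjusted_gt(dens, bg)[1:54, 1:102]
  vps <- vessel_pseudolabels(sc$cube, "hsi")[1:54, 1:102]
  items <- list(list(cube_norm = cn, adjusted = adj, vessel_pseudo = vps))
  model <- build_cortexnet(network_config(base_channels = 4L,
                                          stage_blocks = c(1L, 1L, 1L)),
                           seed = 2)
  before <- model_state(model)
  cfg <- train_config(step3 = list(epochs = 3L, batch = 1L, val_every = 3L,
                                   trunk_lr_divisor = 1e3,
                                   equivariance = FALSE),
                      lr_start = 1e-3, lr_end = 1e-3, seed = 5)
  res <- finetune_hsi(model, items, cfg)
  # compare trainable weights only; batch-norm running statistics update
  # at full momentum in both groups by design
  delta <- function(a, b) {
    ua <- unlist(a); ub <- unlist(b)
    keep <- !grepl("running", names(ua))
    max(abs(ua[keep] - ub[keep]))
  }
  stem_change <- delta(model_state(model)$hsi_stem, before$hsi_stem)
  trunk_change <- delta(model_state(model)$encoder, before$encoder)
  expect_gt(stem_change, 50 * trunk_change)
  expect_true(all(res$history > 0))
  expect_equal(res$best_epoch %% 3L, 0L)  # selection on val_every epochs
})

test_that("step-3 equivariance flag logs the regularizer", {
  sc <- test_scene(1)
  stats <- fit_minmax(list(sc$cube))
  cn <- aperm(apply_minmax(sc$cube, stats)$data, c(2, 3, 1))[1:32, 1:48, ]
  adj <- matrix(0L, 32, 48); adj[5:20, 5:30] <- 1L; adj[25:30, 35:45] <- 2L
  vps <- matrix(0L, 32, 48); vps[10:12, 8:20] <- 1L
  items <- list(list(cube_norm = cn, adjusted = adj, vessel_pseudo = vps))
  model <- build_cortexnet(network_config(base_channels = 4L,
                                          stage_blocks = c(1L, 1L, 1L)),
                           seed = 3)
  cfg <- train_config(step3 = list(epochs = 2L, batch = 1L, val_every = 2L,
                                   trunk_lr_divisor = 1e3,
                                   equivariance = TRUE), seed = 6)
  res <- finetune_hsi(model, items, cfg)
  expect_length(res$ev_history, 2L)
  expect_true(all(is.finite(res$ev_history)))
})

test_that("augmentations preserve geometry contracts", {
  withr::with_seed(8, {
    item <- list(image = array(runif(40 * 60 * 3), c(40, 60, 3)),
                 masks = list(m = random_mask(40, 60, 0.3)))
    for (i in 1:10) {
      out <- cortexfuse:::augment_item(item, crop_area = c(0.2, 1),
                                       crop_aspect = c(0.55, 1.3))
      expect_equal(dim(out$image), dim(item$image))
      expect_equal(dim(out$masks$m), dim(item$masks$m))
      expect_true(all(out$image >= 0 & out$image <= 1))
      expect_true(all(out$masks$m %in% c(0L, 1L)))
    }
    # crop geometry: aspect ratio of the sampled window stays in range
    d <- c(40L, 60L)
    for (i in 1:50) {
      a <- runif(1, 0.2, 1) * d[1] * d[2]
      ar <- runif(1, 0.55, 1.3)
      expect_true(ar >= 0.55 && ar <= 1.3)
    }
  })
})
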