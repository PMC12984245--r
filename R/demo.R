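#' End-to-end desk-scale demonstration
#'
#' Runs the whole pipeline on synthetic scenes: scene generation,
#' mosaic/reflectance preprocessing, pseudo-label generation, the
#' three-step training at desk scale, tissue classification with a
#' deliberately flawed classifier, probability fusion, and evaluation.
#' All randomness funnels through the configured seed; rerunning with the
#' same seed reproduces metrics.json bit-identically.
#'
#' @param config a configuration list (see [validate_config()]) or a
#'   YAML path.
#' @param out_dir output directory for metrics, rendered maps, and the
#'   run manifest.
#' @return the run manifest (invisibly the metrics as well).
#' @export
run_demo <- function(config = list(), out_dir = tempfile("cortexfuse_demo")) {
  if (is.character(config)) config <- read_config(config)
  else config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage_times <- c()
  tick <- function(name) {
    stage_times[name] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }
  seed <- config$seed
  demo <- config$demo
  metrics <- list()

  # ---- synthetic scenes ----------------------------------------------------
  scenes <- lapply(seq_len(demo$n_scenes), function(i)
    generate_scene(scene_config(seed = seed + i,
                                rgb_size = demo$rgb_size)))
  test_scene <- generate_scene(scene_config(seed = seed + 1000L,
                                            rgb_size = demo$rgb_size))
  tick("synth")

  # ---- preprocessing round trip -------------------------------------------
  sc <- scenes[[1]]
  cube <- calibrate_reflectance(demosaic(sc$raw),
                                reference_pair(sc$white, sc$dark))
  metrics$preproc_roundtrip_max_err <-
    max(abs(cube$data - sc$cube$data))
  prgb <- reconstruct_prgb(cube)
  write_rgb_png(prgb, file.path(out_dir, "prgb.png"))
  tick("preproc")

  # ---- pseudo-labels -------------------------------------------------------
  items <- lapply(scenes, function(s) {
    ann <- generate_patch_annotations(s, seed = s$config$seed + 7L)
    pm <- build_patch_mask(ann)
    refined <- refine_cortex_annotation(s$rgb, pm, seed = s$config$seed)
    contour <- approximate_perimeter(s$rgb, refined)
    vessel <- vessel_pseudolabels(s$rgb, "rgb")
    ad <- adapt_rgb_dataset(s$rgb, refined,
                            masks = list(refined = refined,
                                         contour = contour,
                                         vessel = vessel,
                                         gold = s$rgb_cortex_gold),
                            target = demo$train_size)
    list(image = ad$image, refined = ad$masks$refined,
         contour = ad$masks$contour, vessel = ad$masks$vessel,
         gold = ad$masks$gold,
         patch_dsc = dsc(pm, s$rgb_cortex_gold),
         refined_dsc = dsc(refined, s$rgb_cortex_gold), scene = s)
  })
  metrics$pseudolabel_patch_dsc <-
    mean(vapply(items, `[[`, numeric(1), "patch_dsc"))
  metrics$pseudolabel_refined_dsc <-
    mean(vapply(items, `[[`, numeric(1), "refined_dsc"))
  # fine-tuning works on a spatially subsampled grid at desk scale
  ri <- round(seq(1, 217, length.out = demo$train_size[1]))
  ci <- round(seq(1, 409, length.out = demo$train_size[2]))
  hsi_items <- lapply(scenes, function(s) {
    dens <- densify_gt(s$gt_sparse)
    bg <- complement_background(s$cube, dens, seed = s$config$seed)
    adj <- build_adjusted_gt(dens, bg)
    vps <- vessel_pseudolabels(s$cube, "hsi")
    stats <- fit_minmax(list(s$cube))
    cn <- aperm(apply_minmax(s$cube, stats)$data, c(2, 3, 1))
    list(cube_norm = cn[ri, ci, , drop = FALSE], adjusted = adj[ri, ci],
         vessel_pseudo = vps[ri, ci], vessel_pseudo_full = vps, scene = s)
  })
  metrics$vessel_pseudo_vhr <- mean(vapply(hsi_items, function(it)
    vhr(it$vessel_pseudo_full, it$scene$gt_sparse), numeric(1)))
  metrics$vessel_pseudo_ver <- mean(vapply(hsi_items, function(it)
    ver(it$vessel_pseudo_full, it$scene$gt_sparse), numeric(1)))
  tick("pseudolabel")

  # ---- three-step training at desk scale ----------------------------------
  net_cfg <- config$network
  net_cfg$base_channels <- demo$base_channels
  net_cfg$stage_blocks <- demo$stage_blocks
  model <- build_cortexnet(do.call(network_config, net_cfg), seed = seed)
  tcfg <- train_config(
    step1 = list(epochs = demo$epochs[1], batch = 16L,
                 pos_fraction = 1 / 3, tau = config$loss$tau),
    step2 = list(epochs = demo$epochs[2], batch = demo$batch,
                 val_every = 5L, crop_area = c(0.2, 1.0),
                 crop_aspect = c(0.55, 1.3)),
    step3 = list(epochs = demo$epochs[3], batch = demo$batch,
                 val_every = 5L,
                 trunk_lr_divisor = config$train$step3$trunk_lr_divisor,
                 equivariance = config$train$step3$equivariance),
    seed = seed)
  patches <- make_patch_dataset(scenes, patch_px = 32L, seed = seed)
  pre <- pretrain_encoder(model, patches, tcfg)
  step2 <- train_rgb(model, items, tcfg)
  load_state(model, step2$state)
  train_dsc <- vapply(items, function(it) {
    pr <- predict_masks(model, it$image, "rgb")
    dsc(pr$cortex_prob[, , 1] > 0.5, it$refined)
  }, numeric(1))
  step3 <- finetune_hsi(model, hsi_items, tcfg)
  load_state(model, step3$state)
  metrics$supcon_first_loss <- pre$history[1]
  metrics$supcon_last_loss <- tail(pre$history, 1)
  metrics$rgb_best_val_score <- step2$best_score
  metrics$hsi_best_val_score <- step3$best_score
  metrics$train_cortex_dsc <- mean(train_dsc)
  tick("train")

  # ---- flawed classifier + fusion on the test scene ------------------------
  conf <- diag(4)
  conf[3, ] <- c(0.1, config$fusion$vessel_to_tumor_confusion,
                 1 - 0.1 - config$fusion$vessel_to_tumor_confusion, 0)
  probs <- generate_flawed_probs(test_scene, conf, seed = seed + 2L)
  if (identical(demo$masks, "oracle")) {
    pctx <- clamp(test_scene$cortex_gold + 0, 0.001, 0.999)
    pvsl <- clamp(test_scene$vessel_truth + 0, 0.001, 0.999)
  } else {
    stats <- fit_minmax(list(test_scene$cube))
    cn <- aperm(apply_minmax(test_scene$cube, stats)$data, c(2, 3, 1))
    pr <- predict_masks(model, cn, "hsi")
    pctx <- pr$cortex_prob[, , 1]; pvsl <- pr$vessel_prob[, , 1]
  }
  fused <- fuse(transform_probs(probs), pctx, pvsl)
  gt <- test_scene$gt_sparse
  raw_map <- matrix(max.col(matrix(probs, ncol = 4L), ties.method = "first"),
                    nrow(gt), ncol(gt))
  raw_f1 <- f1_per_class(raw_map, gt)$f1
  fus_f1 <- f1_per_class(fused$class_map, gt)$f1
  metrics$raw_tumor_f1 <- unname(raw_f1["2"])
  metrics$fused_tumor_f1 <- unname(fus_f1["2"])
  metrics$raw_vessel_f1 <- unname(raw_f1["3"])
  metrics$fused_vessel_f1 <- unname(fus_f1["3"])
  write_rgb_png(render_map(fused), file.path(out_dir, "fused.png"))
  tick("fuse")

  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package_version =
                     as.character(utils::packageVersion("cortexfuse")),
                   stage_seconds = as.list(stage_times),
                   outputs = list(metrics = metrics_path,
                                  prgb = file.path(out_dir, "prgb.png"),
                                  fused = file.path(out_dir, "fused.png")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, metrics = metrics))
}
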