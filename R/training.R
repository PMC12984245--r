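#' Multimodal transfer-training pipeline
#'
#' Orchestrates the three training steps: (1) supervised-contrastive
#' pre-training of the encoder on positive/negative patches, (2) training
#' of the encoder-decoder on the RGB dataset with the compound
#' pseudo-label losses, and (3) HSI fine-tuning of the spectral stem with
#' the trunk learning rate divided by 1000, against the adjusted ground
#' truth and masked vessel pseudo-labels.  AdamW with cosine learning-rate
#' decay (1e-4 down to 1e-5) drives all steps; model selection evaluates
#' the validation set every `val_every` epochs and keeps the best
#' checkpoint.
#'
#' @name training_pipeline
NULL

#' Training configuration
#'
#' Defaults are the full-scale settings; tests and the demo pass reduced
#' epoch counts through the same structure.
#'
#' @param step1,step2,step3 per-step lists; see the defaults.
#' @param lr_start,lr_end cosine learning-rate decay endpoints.
#' @param weight_decay AdamW weight decay.
#' @param seed integer RNG seed.
#' @export
train_config <- function(
    step1 = list(epochs = 400L, batch = 128L, pos_fraction = 1 / 3,
                 tau = 0.1),
    step2 = list(epochs = 1000L, batch = 8L, val_every = 10L,
                 crop_area = c(0.2, 1.0), crop_aspect = c(0.55, 1.3)),
    step3 = list(epochs = 700L, batch = 8L, val_every = 10L,
                 trunk_lr_divisor = 1e3, equivariance = FALSE),
    lr_start = 1e-4, lr_end = 1e-5, weight_decay = 0.01, seed = 0L) {
  stopifnot(step1$epochs >= 1L, step2$epochs >= 1L, step3$epochs >= 1L,
            step1$pos_fraction > 0, step1$pos_fraction < 1)
  list(step1 = step1, step2 = step2, step3 = step3, lr_start = lr_start,
       lr_end = lr_end, weight_decay = weight_decay,
       seed = as.integer(seed))
}

#' Patient-level cross-validation splits
#'
#' The test set is a fixed, rounded-down 20% of the cohort; the remaining
#' patients are re-split into training and validation for each fold (the
#' validation count is the rounded validation fraction of the full
#' cohort).  A 67-patient cohort gives 13 test / 47 train / 7 validation.
#'
#' @param patient_ids vector of identifiers.
#' @param fractions `(train, val, test)` fractions.
#' @param n_folds number of folds sharing the same test set.
#' @param seed integer RNG seed.
#' @return list of folds, each with `train`, `val`, `test`.
#' @export
make_splits <- function(patient_ids, fractions = c(0.70, 0.10, 0.20),
                        n_folds = 5L, seed = 0L) {
  n <- length(patient_ids)
  if (n < n_folds) stop("fewer patients than folds")
  n_test <- floor(fractions[3] * n)
  n_val <- round(fractions[2] * n)
  if (n_test < 1L || n_val < 1L || n - n_test - n_val < 1L)
    stop("cohort too small for the requested fractions")
  withr::with_seed(seed, {
    test <- sort(sample(patient_ids, n_test))
    rest <- setdiff(patient_ids, test)
    lapply(seq_len(n_folds), function(f) {
      val <- sort(sample(rest, n_val))
      list(train = setdiff(rest, val), val = val, test = test)
    })
  })
}

# ---- data augmentation -----------------------------------------------------

jitter_rgb <- function(img) {
  scale <- runif(3, 0.8, 1.2)
  shift <- runif(3, -0.08, 0.08)
  for (k in 1:3) img[, , k] <- img[, , k] * scale[k] + shift[k]
  clamp(img, 0, 1)
}

blur_rgb <- function(img) {
  s <- runif(1, 0.5, 1.5)
  for (k in seq_len(dim(img)[3]))
    img[, , k] <- ebi_data(EBImage::gblur(img[, , k], sigma = s))
  clamp(img, 0, 1)
}

flip_item <- function(item, type) {
  d <- dim(item$image)
  ix <- flip_idx(d, type)
  item$image <- item$image[ix[[1]], ix[[2]], , drop = FALSE]
  for (nm in names(item$masks))
    item$masks[[nm]] <- item$masks[[nm]][ix[[1]], ix[[2]], drop = FALSE]
  item
}

crop_resize_item <- function(item, area_range, aspect_range) {
  d <- dim(item$image)
  for (try in 1:10) {
    a <- runif(1, area_range[1], area_range[2]) * d[1] * d[2]
    ar <- runif(1, aspect_range[1], aspect_range[2]) * d[2] / d[1]
    ch <- round(sqrt(a / ar)); cw <- round(sqrt(a * ar))
    if (ch >= 8 && cw >= 8 && ch <= d[1] && cw <= d[2]) {
      top <- sample.int(d[1] - ch + 1L, 1L)
      left <- sample.int(d[2] - cw + 1L, 1L)
      rows <- top:(top + ch - 1L); cols <- left:(left + cw - 1L)
      item$image <- resize_rgb(item$image[rows, cols, , drop = FALSE],
                               d[1:2])
      for (nm in names(item$masks))
        item$masks[[nm]] <- as_mask(
          resize_mat(item$masks[[nm]][rows, cols, drop = FALSE],
                     d[1:2], "nearest"))
      return(item)
    }
  }
  item
}

# augmentation for step-2 items (image + masks); each transform fires with
# probability 1/2
augment_item <- function(item, crop_area = NULL, crop_aspect = NULL,
                         flips_only = FALSE) {
  if (runif(1) < 0.5) item <- flip_item(item, "hflip")
  if (runif(1) < 0.5) item <- flip_item(item, "vflip")
  if (flips_only) return(item)
  if (runif(1) < 0.5) item$image <- jitter_rgb(item$image)
  if (runif(1) < 0.5) item$image <- blur_rgb(item$image)
  if (!is.null(crop_area) && runif(1) < 0.5)
    item <- crop_resize_item(item, crop_area, crop_aspect)
  item
}

augment_patch <- function(img) {
  d <- dim(img)
  if (runif(1) < 0.5) img <- img[, rev(seq_len(d[2])), , drop = FALSE]
  if (runif(1) < 0.5) img <- img[rev(seq_len(d[1])), , , drop = FALSE]
  if (runif(1) < 0.5) img <- jitter_rgb(img)
  if (runif(1) < 0.5) img <- blur_rgb(img)
  img
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Build a positive/negative patch dataset from synthetic scenes
#'
#' Positive patches come from the weak cortex annotations, negatives from
#' the margin-safe sampler outside them; all are resized to a common
#' square size.
#'
#' @param scenes list of `scene_pack`s.
#' @param patch_px output patch side length.
#' @param seed integer RNG seed.
#' @return list with `images` (list of `(p, p, 3)` arrays) and binary
#'   `labels` (1 positive, 0 negative).
#' @export
make_patch_dataset <- function(scenes, patch_px = 32L, seed = 0L) {
  withr::with_seed(seed, {
    images <- list(); labels <- integer()
    for (sc in scenes) {
      ann <- generate_patch_annotations(sc, seed = sample.int(1e6, 1))
      pm <- build_patch_mask(ann)
      p <- ann$positive_patches
      for (i in seq_len(nrow(p))) {
        rows <- p$top[i]:(p$top[i] + p$size[i] - 1L)
        cols <- p$left[i]:(p$left[i] + p$size[i] - 1L)
        images[[length(images) + 1L]] <-
          resize_rgb(sc$rgb[rows, cols, , drop = FALSE],
                     c(patch_px, patch_px))
        labels <- c(labels, 1L)
      }
      neg_size <- min(nrow(sc$rgb) %/% 4L, 217L)
      neg <- sample_negative_patches(pm, patch_size = neg_size,
                                     margin = min(108L, neg_size %/% 2L),
                                     seed = sample.int(1e6, 1))
      for (i in seq_len(nrow(neg))) {
        rows <- neg$top[i]:(neg$top[i] + neg$size[i] - 1L)
        cols <- neg$left[i]:(neg$left[i] + neg$size[i] - 1L)
        images[[length(images) + 1L]] <-
          resize_rgb(sc$rgb[rows, cols, , drop = FALSE],
                     c(patch_px, patch_px))
        labels <- c(labels, 0L)
      }
    }
    list(images = images, labels = labels)
  })
}

#' Step 1: supervised-contrastive encoder pre-training
#'
#' Batches are composed of `round(batch * pos_fraction)` positive patches
#' and negatives for the remainder; each patch receives random flips,
#' color jitter and Gaussian blur (probability 1/2 each; no random
#' cropping, the patches already being crops).  The projection head is
#' used for the loss and discarded afterwards.
#'
#' @param model a `cortexnet`.
#' @param patch_dataset from [make_patch_dataset()].
#' @param config a [train_config()].
#' @return list with the final `state`, the per-epoch `history`, and the
#'   batch composition.
#' @export
pretrain_encoder <- function(model, patch_dataset, config = train_config()) {
  cfg <- config$step1
  pos_idx <- which(patch_dataset$labels == 1L)
  neg_idx <- which(patch_dataset$labels == 0L)
  if (length(pos_idx) == 0L || length(neg_idx) == 0L)
    stop("patch dataset must contain both positive and negative patches")
  n_pos <- max(1L, round(cfg$batch * cfg$pos_fraction))
  n_neg <- cfg$batch - n_pos
  params <- model_params(model, c("rgb_stem", "encoder", "projection"))
  history <- numeric(cfg$epochs)
  withr::with_seed(config$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cosine_lr(ep, cfg$epochs, config$lr_start, config$lr_end)
      bp <- sample(pos_idx, n_pos, replace = n_pos > length(pos_idx))
      bn <- sample(neg_idx, n_neg, replace = n_neg > length(neg_idx))
      idx <- c(bp, bn)
      imgs <- lapply(patch_dataset$images[idx], augment_patch)
      x <- stack_images(imgs)
      z <- project_embedding(model, x, "rgb", training = TRUE,
                             as_value = FALSE)
      loss <- supcon_loss(z, patch_dataset$labels[idx], cfg$tau)
      zero_grads(params)
      agt_backward(loss)
      adamw_step(list(list(params = params, lr = lr)),
                 weight_decay = config$weight_decay)
      history[ep] <- loss$value
    }
  })
  list(state = model_state(model), history = history,
       batch_composition = c(pos = n_pos, neg = n_neg))
}

masks_to_items <- function(rgb_dataset) {
  lapply(rgb_dataset, function(it)
    list(image = it$image,
         masks = list(refined = as_mask(it$refined),
                      contour = as_mask(it$contour),
                      vessel = as_mask(it$vessel))))
}

validate_rgb <- function(model, items) {
  scores <- vapply(items, function(it) {
    pr <- predict_masks(model, it$image, "rgb")
    mean(c(dsc(pr$cortex_prob[, , 1] > 0.5, it$masks$refined),
           dsc(pr$vessel_prob[, , 1] > 0.5, it$masks$vessel)))
  }, numeric(1))
  mean(scores)
}

#' Step 2: RGB encoder-decoder training
#'
#' Trains on the compound [total_rgb_loss()] with flips, color jitter,
#' blur and random resized crops (area and aspect ranges per the
#' configuration).  Every `val_every` epochs the mean of the cortex DSC
#' (against the refined annotations) and the vessel DSC (against the
#' vessel pseudo-labels) is computed on the validation items and the best
#' model is kept.
#'
#' @param model a `cortexnet` (optionally with a pre-trained encoder
#'   loaded).
#' @param rgb_dataset list of items with `image`, `refined`, `contour`,
#'   `vessel` (see [adapt_rgb_dataset()]).
#' @param config a [train_config()].
#' @param val_dataset optional held-out items in the same format
#'   (defaults to the training items).
#' @return list with the best `state`, its `best_epoch` and `best_score`,
#'   and the loss `history`.
#' @export
train_rgb <- function(model, rgb_dataset, config = train_config(),
                      val_dataset = NULL) {
  cfg <- config$step2
  items <- masks_to_items(rgb_dataset)
  val_items <- if (is.null(val_dataset)) items
               else masks_to_items(val_dataset)
  params <- model_params(model, c("rgb_stem", "encoder", "decoder", "head"))
  history <- numeric(cfg$epochs)
  best <- list(score = -Inf, state = model_state(model), epoch = 0L)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cosine_lr(ep, cfg$epochs, config$lr_start, config$lr_end)
      idx <- sample(seq_along(items),
                    min(cfg$batch, length(items)))
      loss_sum <- 0
      zero_grads(params)
      for (i in idx) {
        it <- if (isTRUE(cfg$augment %||% TRUE))
          augment_item(items[[i]], cfg$crop_area, cfg$crop_aspect)
        else items[[i]]
        x <- array(it$image, c(dim(it$image), 1L))
        out <- net_forward(model, x, "rgb", training = TRUE)
        cp <- agt_channel(out$probs, 1L)
        vp <- agt_channel(out$probs, 2L)
        cp2 <- agt_index_plane(cp, 1L)
        vp2 <- agt_index_plane(vp, 1L)
        comps <- total_rgb_loss(list(cortex_prob = cp2, vessel_prob = vp2),
                                it$masks, loss_config())
        loss <- comps$total / length(idx)
        agt_backward(loss)
        loss_sum <- loss_sum + loss$value * length(idx)
      }
      adamw_step(list(list(params = params, lr = lr)),
                 weight_decay = config$weight_decay)
      history[ep] <- loss_sum / length(idx)
      if (ep %% cfg$val_every == 0L || ep == cfg$epochs) {
        sc <- validate_rgb(model, val_items)
        if (sc > best$score)
          best <- list(score = sc, state = model_state(model), epoch = ep)
      }
    }
  })
  list(state = best$state, best_epoch = best$epoch,
       best_score = best$score, history = history)
}

validate_hsi <- function(model, items) {
  scores <- vapply(items, function(it) {
    pr <- predict_masks(model, it$cube_norm, "hsi")
    sel <- it$adjusted != ADJ_UNKNOWN
    acc <- mean((pr$cortex_prob[, , 1] > 0.5)[sel] ==
                  (it$adjusted == ADJ_INNER)[sel]) * 100
    inner_pseudo <- as_mask(it$vessel_pseudo * (it$adjusted == ADJ_INNER))
    vd <- dsc((pr$vessel_prob[, , 1] > 0.5) * (it$adjusted == ADJ_INNER),
              inner_pseudo)
    mean(c(acc, vd))
  }, numeric(1))
  mean(scores)
}

#' Step 3: HSI fine-tuning of the spectral stem
#'
#' The HSI stem trains at the full learning rate; every other layer's
#' rate is divided by `trunk_lr_divisor` (1000), so the trunk adapts
#' minimally while its batch-norm running statistics adjust to the HS
#' data.  The loss is the masked cortex BCE against the adjusted ground
#' truth plus the masked vessel BCE (optionally plus the equivariance
#' term); augmentation is horizontal/vertical flips only.  Selection
#' averages the cortex accuracy on inner/outer pixels with the vessel DSC
#' against the masked pseudo-labels.
#'
#' @param model a `cortexnet` with an RGB-trained trunk loaded.
#' @param hsi_dataset list of items with `cube_norm` (h, w, bands),
#'   `adjusted`, `vessel_pseudo`.
#' @param config a [train_config()].
#' @param val_dataset optional held-out items.
#' @return list with the best `state`, `best_epoch`, `best_score`, the
#'   loss `history`, and the equivariance history when enabled.
#' @export
finetune_hsi <- function(model, hsi_dataset, config = train_config(),
                         val_dataset = NULL) {
  cfg <- config$step3
  items <- hsi_dataset
  val_items <- if (is.null(val_dataset)) items else val_dataset
  stem_params <- model_params(model, "hsi_stem")
  trunk_params <- model_params(model, c("rgb_stem", "encoder", "decoder",
                                        "head"))
  all_params <- c(stem_params, trunk_params)
  history <- numeric(cfg$epochs)
  ev_history <- if (isTRUE(cfg$equivariance)) numeric(cfg$epochs) else NULL
  best <- list(score = -Inf, state = model_state(model), epoch = 0L)
  withr::with_seed(config$seed + 2L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cosine_lr(ep, cfg$epochs, config$lr_start, config$lr_end)
      idx <- sample(seq_along(items), min(cfg$batch %||% 8L, length(items)))
      loss_sum <- 0
      zero_grads(all_params)
      for (i in idx) {
        it <- items[[i]]
        tp <- if (isTRUE(cfg$augment %||% TRUE))
          sample(c("identity", "hflip", "vflip"), 1L) else "identity"
        d <- dim(it$cube_norm)
        ix <- flip_idx(d, if (tp == "identity") "identity" else tp)
        cube <- it$cube_norm[ix[[1]], ix[[2]], , drop = FALSE]
        adj <- it$adjusted[ix[[1]], ix[[2]]]
        vps <- it$vessel_pseudo[ix[[1]], ix[[2]]]
        x <- array(cube, c(d, 1L))
        out <- net_forward(model, x, "hsi", training = TRUE)
        cp <- agt_index_plane(agt_channel(out$probs, 1L), 1L)
        vp <- agt_index_plane(agt_channel(out$probs, 2L), 1L)
        loss <- masked_cortex_bce(cp, adj) + masked_vessel_bce(vp, vps, adj)
        if (isTRUE(cfg$equivariance)) {
          ev <- equivariance_loss(model, x, "hsi",
                                  seed = sample.int(1e6, 1))
          loss <- loss + ev
          ev_history[ep] <- ev_history[ep] + agt_value(ev) / length(idx)
        }
        loss <- loss / length(idx)
        agt_backward(loss)
        loss_sum <- loss_sum + agt_value(loss) * length(idx)
      }
      adamw_step(list(
        list(params = stem_params, lr = lr),
        list(params = trunk_params, lr = lr / cfg$trunk_lr_divisor)),
        weight_decay = config$weight_decay)
      history[ep] <- loss_sum / length(idx)
      if (ep %% cfg$val_every == 0L || ep == cfg$epochs) {
        sc <- validate_hsi(model, val_items)
        if (sc > best$score)
          best <- list(score = sc, state = model_state(model), epoch = ep)
      }
    }
  })
  list(state = best$state, best_epoch = best$epoch,
       best_score = best$score, history = history,
       ev_history = ev_history)
}
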