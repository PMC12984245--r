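#' Configuration handling
#'
#' A single YAML-style configuration tree drives the command-line
#' pipeline; every documented hyperparameter is a default here, never
#' hard-coded elsewhere.
#'
#' @name app_config
NULL

#' Full default configuration
#'
#' @return nested list of defaults: losses (alpha 10, tau 0.1), training
#'   (epochs 400 / 1000 / 700, batches 128 / 8 / 8, cosine learning rate
#'   1e-4 to 1e-5, trunk divisor 1000), pseudo-label parameters, network
#'   shape, and the desk-scale demo profile.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    loss = list(alpha = 10, tau = 0.1, binarize_threshold = 0.5),
    train = list(
      step1 = list(epochs = 400L, batch = 128L, pos_fraction = 1 / 3),
      step2 = list(epochs = 1000L, batch = 8L, val_every = 10L,
                   crop_area = c(0.2, 1.0), crop_aspect = c(0.55, 1.3)),
      step3 = list(epochs = 700L, batch = 8L, val_every = 10L,
                   trunk_lr_divisor = 1e3, equivariance = FALSE),
      lr_start = 1e-4, lr_end = 1e-5),
    network = list(base_channels = 8L, stage_blocks = c(4L, 4L, 6L),
                   embedding_dim = 256L, hsi_in_bands = 25L,
                   leaky_slope = 0.01),
    pseudolabel = list(k_clusters = 12L, centroid_mult = 3,
                       n_background = 8L, rgb_k_thin = 7L,
                       rgb_k_thick = 15L, hsi_k_thin = 5L,
                       hsi_k_thick = 11L, n_orientations = 12L,
                       threshold_quantile = 0.90, rgb_min_area = 40L,
                       hsi_min_area = 10L, hsi_band = 4L,
                       patch_size = 217L, margin = 108L,
                       mask_fraction = 0.20),
    fusion = list(vessel_to_tumor_confusion = 0.8),
    demo = list(n_scenes = 4L, rgb_size = c(540L, 960L),
                epochs = c(10L, 30L, 10L), batch = 4L,
                base_channels = 8L, stage_blocks = c(2L, 2L, 2L),
                train_size = c(109L, 205L), masks = "oracle")
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      warning(sprintf("unknown configuration key '%s' ignored", key))
      next
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate and normalize a configuration
#'
#' Fills missing keys with defaults, checks value ranges, and warns on
#' unknown keys.
#'
#' @param config partial configuration list (e.g. parsed from YAML).
#' @return normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  cfg <- merge_config(default_config(), config)
  if (cfg$loss$alpha <= 0) stop("loss.alpha must be > 0")
  if (cfg$loss$tau <= 0) stop("loss.tau must be > 0")
  if (cfg$loss$binarize_threshold <= 0 || cfg$loss$binarize_threshold >= 1)
    stop("loss.binarize_threshold must be in (0, 1)")
  for (s in c("step1", "step2", "step3"))
    if (cfg$train[[s]]$epochs < 1L)
      stop(sprintf("train.%s.epochs must be >= 1", s))
  if (cfg$pseudolabel$k_clusters <= cfg$pseudolabel$n_background)
    stop("pseudolabel.k_clusters must exceed pseudolabel.n_background")
  if (cfg$train$step3$trunk_lr_divisor <= 0)
    stop("train.step3.trunk_lr_divisor must be > 0")
  cfg
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file path (missing file gives the full defaults).
#' @export
read_config <- function(path = NULL) {
  user <- if (!is.null(path) && file.exists(path))
    yaml::read_yaml(path) else list()
  validate_config(user)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(rapply(config, unclass, how = "replace"), f)
  unname(tools::md5sum(f))
}
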