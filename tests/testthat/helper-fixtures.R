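# Shared fixtures, built once per test run.  Scenes use a reduced RGB
# resolution (270 x 480) so the suite stays fast; the generator's defaults
# are unchanged.

.fixtures <- new.env(parent = emptyenv())

test_scene <- function(seed = 1L, rgb_size = c(270L, 480L), ...) {
  key <- paste0("scene_", seed, "_", paste(rgb_size, collapse = "x"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_scene(
      scene_config(seed = seed, rgb_size = rgb_size, ...))
  .fixtures[[key]]
}

# a filled disc mask
disc_mask <- function(h, w, cy, cx, r) {
  m <- (row(matrix(0, h, w)) - cy)^2 + (col(matrix(0, h, w)) - cx)^2 <= r^2
  m * 1L
}

# random binary mask with given density
random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# brute-force all-pairs nearest boundary distance (ASSD oracle)
assd_bruteforce <- function(a, b) {
  ba <- which(cortexfuse:::boundary_4(a) == 1L, arr.ind = TRUE)
  bb <- which(cortexfuse:::boundary_4(b) == 1L, arr.ind = TRUE)
  d_ab <- vapply(seq_len(nrow(ba)), function(i)
    sqrt(min((bb[, 1] - ba[i, 1])^2 + (bb[, 2] - ba[i, 2])^2)), numeric(1))
  d_ba <- vapply(seq_len(nrow(bb)), function(i)
    sqrt(min((ba[, 1] - bb[i, 1])^2 + (ba[, 2] - bb[i, 2])^2)), numeric(1))
  (mean(d_ab) + mean(d_ba)) / 2
}
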