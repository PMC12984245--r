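#' File interchange helpers
#'
#' Masks and label maps travel as single-channel PNGs (label codes stored
#' as small integer pixel values), RGB images as PNGs, and cubes as RDS
#' files (band-major arrays plus wavelengths), the R-native counterpart
#' of array archives.
#'
#' @name io
NULL

#' @rdname io
#' @param mask binary or small-integer label matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as.matrix(mask) / 255, path)
  invisible(path)
}

#' @rdname io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 255)
}

#' @rdname io
#' @param img `(h, w, 3)` array in `[0, 1]`.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' @rdname io
#' @param cube an [hsi_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  saveRDS(unclass(cube), path)
  invisible(path)
}

#' @rdname io
#' @export
read_cube <- function(path) {
  x <- readRDS(path)
  hsi_cube(x$data, x$wavelengths_nm, x$calibrated)
}

#' Write a cube as an ENVI-style header + flat binary pair
#'
#' Band-sequential (BSQ) float32 raw data with a plain-text header, for
#' interoperability with external HSI tools.
#'
#' @param cube an [hsi_cube()].
#' @param path base path; `.hdr` and `.raw` are appended.
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[3]),
           sprintf("lines = %d", d[2]),
           sprintf("bands = %d", d[1]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq", "byte order = 0",
           paste0("wavelength = {",
                  paste(cube$wavelengths_nm, collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  # BSQ: per band, row-major lines
  for (b in seq_len(d[1]))
    writeBin(as.vector(t(cube$data[b, , ])), con, size = 4L)
  invisible(path)
}
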