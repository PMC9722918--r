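#' Calibrated 2-D intensity image
#'
#' A single-channel grayscale image together with its physical pixel size.
#' All segmentation and morphology functions operate on this container so
#' that geometric parameters can be expressed in micrometres independently of
#' the sampling resolution.
#'
#' @param intensities numeric matrix of non-negative, finite pixel values
#'   (rows = y, columns = x).
#' @param pixel_size_um physical size of one pixel edge, in micrometres
#'   (must be > 0).
#' @param bit_depth free-text note on the native bit depth of the source
#'   (e.g. `"16-bit"`, `"float"`). Informational only.
#' @return An object of class `calibrated_image`: a list with elements
#'   `intensities`, `pixel_size_um` and `bit_depth`.
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8, 8), pixel_size_um = 0.1)
#' dim(img$intensities)
#' @export
calibrated_image <- function(intensities, pixel_size_um, bit_depth = "float") {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stopf("'intensities' must be a numeric matrix")
  if (!all(is.finite(intensities)))
    stopf("'intensities' must be finite")
  if (!is_number(pixel_size_um) || pixel_size_um <= 0)
    stopf("'pixel_size_um' must be a single positive number")
  structure(
    list(intensities = intensities,
         pixel_size_um = pixel_size_um,
         bit_depth = bit_depth),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%s)\n",
              d[1], d[2], x$pixel_size_um, x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

as_calibrated_image <- function(x, pixel_size_um = NULL) {
  if (inherits(x, "calibrated_image")) return(x)
  if (is.null(pixel_size_um))
    stopf("a plain matrix needs an explicit 'pixel_size_um'")
  calibrated_image(x, pixel_size_um)
}

#' Read a single-channel TIFF as a calibrated image
#'
#' The pixel size is never inferred from file metadata; it must be given
#' explicitly.
#'
#' @param path path to an 8- or 16-bit single-channel TIFF file.
#' @param pixel_size_um micrometres per pixel.
#' @return A [calibrated_image()] with intensities on the native integer
#'   scale of the file.
#' @export
read_calibrated_tiff <- function(path, pixel_size_um) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] != 1L)
      stopf("%s: expected a single-channel image, found %d channels",
            path, dim(raw)[3])
    raw <- raw[, , 1L]
  }
  bits <- attr(raw, "bits.per.sample")
  calibrated_image(raw, pixel_size_um,
                   bit_depth = if (is.null(bits)) "unknown"
                               else paste0(bits, "-bit"))
}

#' Write a calibrated image or a label map as 16-bit TIFF
#'
#' Intensities (or labels) are written on the 16-bit integer scale; values
#' are clipped to `[0, 65535]`.
#'
#' @param x a [calibrated_image()] or an integer label matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(x, path) {
  m <- if (inherits(x, "calibrated_image")) x$intensities else x
  m <- pmin(pmax(round(m), 0), 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
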