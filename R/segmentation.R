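#' Segmentation parameters
#'
#' All geometric parameters are expressed in micrometres (or um^2) and are
#' converted to pixels internally using the image calibration, so the same
#' parameter set behaves identically across pixel sizes.
#'
#' @param cell_smooth_sigma_um Gaussian sigma for cell-mask smoothing, um.
#' @param threshold_method `"otsu"` (default), `"isodata"` (ImageJ-style
#'   iterative intermeans) or `"fixed"`.
#' @param fixed_threshold threshold on the raw intensity scale, used when
#'   `threshold_method = "fixed"`.
#' @param bandpass_sigma_small_um,bandpass_sigma_large_um
#'   difference-of-Gaussians scales for mitochondrial enhancement; small must
#'   be strictly less than large.
#' @param min_object_area_um2 mitochondrial objects below this area are
#'   removed (tiny-object filter).
#' @param min_cell_area_um2 cell-scale minimum; smaller cell objects removed.
#' @param hmax_prominence_um prominence (in um of distance-transform height)
#'   a regional maximum must have to seed a watershed basin when splitting
#'   touching mitochondria.
#' @param cell_split_prominence_um prominence used when separating touching
#'   cells, um.
#' @param split_enabled whether touching objects are split by the
#'   marker-controlled watershed.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(cell_smooth_sigma_um = 1.0,
                                threshold_method = c("otsu", "isodata", "fixed"),
                                fixed_threshold = NULL,
                                bandpass_sigma_small_um = 0.1,
                                bandpass_sigma_large_um = 1.0,
                                min_object_area_um2 = 0.1,
                                min_cell_area_um2 = 5,
                                hmax_prominence_um = 0.1,
                                cell_split_prominence_um = 1.0,
                                split_enabled = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (bandpass_sigma_small_um >= bandpass_sigma_large_um)
    stopf("'bandpass_sigma_small_um' (%.3g) must be < 'bandpass_sigma_large_um' (%.3g)",
          bandpass_sigma_small_um, bandpass_sigma_large_um)
  if (min_object_area_um2 < 0 || min_cell_area_um2 < 0)
    stopf("minimum areas must be >= 0")
  if (hmax_prominence_um < 0 || cell_split_prominence_um < 0)
    stopf("prominences must be >= 0")
  if (threshold_method == "fixed" && !is_number(fixed_threshold))
    stopf("'fixed_threshold' must be given when threshold_method = 'fixed'")
  structure(
    list(cell_smooth_sigma_um = cell_smooth_sigma_um,
         threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         bandpass_sigma_small_um = bandpass_sigma_small_um,
         bandpass_sigma_large_um = bandpass_sigma_large_um,
         min_object_area_um2 = min_object_area_um2,
         min_cell_area_um2 = min_cell_area_um2,
         hmax_prominence_um = hmax_prominence_um,
         cell_split_prominence_um = cell_split_prominence_um,
         split_enabled = isTRUE(split_enabled)),
    class = "segmentation_params")
}

#' Normalise an image to the full 16-bit range
#'
#' Linear rescaling: the minimum maps to 0 and the maximum to 65535, with
#' round-half-up to integer. A constant image maps to all zeros.
#'
#' @param img a [calibrated_image()].
#' @return A [calibrated_image()] with integer intensities in `[0, 65535]`.
#' @export
normalize_image <- function(img) {
  img <- as_calibrated_image(img)
  x <- img$intensities
  rng <- range(x)
  y <- if (rng[2] == rng[1]) matrix(0, nrow(x), ncol(x))
       else floor((x - rng[1]) / (rng[2] - rng[1]) * 65535 + 0.5)
  calibrated_image(y, img$pixel_size_um, bit_depth = "16-bit")
}

# ImageJ-style isodata (iterative intermeans) threshold on a 256-bin histogram
isodata_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  mids <- (br[-1] + br[-257]) / 2
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = 256L)
  t_old <- -Inf
  t_new <- sum(h * mids) / sum(h)
  for (i in 1:100) {
    lo <- mids <= t_new
    m1 <- if (any(h[lo] > 0)) sum(h[lo] * mids[lo]) / sum(h[lo]) else t_new
    m2 <- if (any(h[!lo] > 0)) sum(h[!lo] * mids[!lo]) / sum(h[!lo]) else t_new
    t_old <- t_new
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t_old) < diff(rng) * 1e-6) break
  }
  t_new
}

# resolve a threshold value for a numeric matrix given the params
auto_threshold <- function(x, params) {
  switch(params$threshold_method,
    fixed = params$fixed_threshold,
    isodata = isodata_threshold(as.numeric(x)),
    otsu = {
      rng <- range(x)
      if (rng[1] == rng[2]) rng[1]
      else {
        sc <- (x - rng[1]) / (rng[2] - rng[1])
        rng[1] + EBImage::otsu(EBImage::Image(sc), range = c(0, 1),
                               levels = 256L) * (rng[2] - rng[1])
      }
    })
}

# drop labelled objects below a pixel-area minimum, keeping label identity
drop_small <- function(labels, min_px) {
  if (min_px <= 0) return(labels)
  tab <- tabulate(labels[labels > 0])
  kill <- which(tab > 0 & tab < min_px)
  if (length(kill)) labels[labels %in% kill] <- 0L
  labels
}

#' Difference-of-Gaussians band-pass filter
#'
#' Enhances tube-like structures of width around `2 * sigma_small_um` while
#' suppressing both pixel noise and smooth background; negative response
#' values are clipped to zero. Calibration is preserved.
#'
#' @param img a [calibrated_image()].
#' @param sigma_small_um,sigma_large_um band edges in um; small < large.
#' @return A [calibrated_image()] holding the clipped DoG response.
#' @export
bandpass_filter <- function(img, sigma_small_um, sigma_large_um) {
  img <- as_calibrated_image(img)
  if (sigma_small_um >= sigma_large_um)
    stopf("'sigma_small_um' (%.3g) must be < 'sigma_large_um' (%.3g)",
          sigma_small_um, sigma_large_um)
  px <- img$pixel_size_um
  lo <- gauss_blur(img$intensities, sigma_small_um / px)
  hi <- gauss_blur(img$intensities, sigma_large_um / px)
  calibrated_image(pmax(lo - hi, 0), px, bit_depth = "float")
}

#' Segment cell bodies
#'
#' Gaussian smoothing, auto-thresholding, hole filling, optional
#' distance-transform watershed separation of touching cells, and removal of
#' objects below the cell-scale minimum area. An all-background result is
#' valid and yields zero labels.
#'
#' @param img a [calibrated_image()].
#' @param params a [segmentation_params()].
#' @return Integer label matrix (0 = background, labels contiguous).
#' @export
segment_cells <- function(img, params = segmentation_params()) {
  img <- as_calibrated_image(img)
  stopifnot(inherits(params, "segmentation_params"))
  px <- img$pixel_size_um
  sm <- gauss_blur(img$intensities, params$cell_smooth_sigma_um / px)
  th <- auto_threshold(sm, params)
  mask <- sm > th
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  labels <- if (params$split_enabled)
    split_touching(mask, params$cell_split_prominence_um, px)
  else {
    l <- EBImage::bwlabel(EBImage::Image(mask * 1))
    matrix(as.integer(round(as.matrix(l))), nrow(mask), ncol(mask))
  }
  labels <- drop_small(labels, params$min_cell_area_um2 / px^2)
  relabel_map(labels)
}

#' Split touching objects by marker-controlled watershed
#'
#' The Euclidean distance transform is computed inside the mask and lightly
#' smoothed (`dt_smooth_px`, default 0.7 px) to suppress the sub-pixel ridge
#' bumps that thin anti-aliased tubes produce; regional maxima whose
#' prominence (height above the saddle connecting them to a higher maximum)
#' is at least `prominence_um` act as markers, and the watershed of the
#' negated distance transform, restricted to the mask, assigns every
#' foreground pixel to exactly one basin. Components with a single
#' sufficiently prominent maximum pass through unchanged, and the output
#' partitions the input mask exactly.
#'
#' @param mask logical or 0/1 matrix (or any label matrix; > 0 is foreground).
#' @param prominence_um minimal maxima prominence in um of distance.
#' @param pixel_size_um micrometres per pixel, used to convert the
#'   prominence to pixels.
#' @param dt_smooth_px Gaussian sigma (in pixels) of the distance-map
#'   regularisation; a discretisation-scale smoothing, hence in pixel units.
#' @return Integer label matrix partitioning `mask > 0`.
#' @export
split_touching <- function(mask, prominence_um = 0.1, pixel_size_um = 0.1,
                           dt_smooth_px = 0.7) {
  fg <- mask > 0
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  dm <- as.matrix(EBImage::distmap(EBImage::Image(fg * 1)))
  if (dt_smooth_px > 0) {
    dm <- gauss_blur(dm, dt_smooth_px)
    dm[!fg] <- 0
  }
  tol <- prominence_um / pixel_size_um
  ws <- EBImage::watershed(EBImage::Image(dm), tolerance = tol, ext = 1L)
  out <- matrix(as.integer(round(as.matrix(ws))), nrow(fg), ncol(fg))
  relabel_map(out)
}

#' Segment mitochondria within cell masks
#'
#' Band-pass enhancement, auto-thresholding, tiny-object removal, optional
#' watershed splitting of touching mitochondria, restriction to pixels inside
#' cell masks, and contiguous relabelling.
#'
#' @param img a [calibrated_image()].
#' @param params a [segmentation_params()].
#' @param cells integer cell label matrix from [segment_cells()] (same shape
#'   as `img`); pass a matrix of ones to disable the restriction.
#' @return Integer mitochondrial label matrix.
#' @export
segment_mitochondria <- function(img, params = segmentation_params(), cells) {
  img <- as_calibrated_image(img)
  stopifnot(inherits(params, "segmentation_params"))
  if (!all(dim(cells) == dim(img$intensities)))
    stopf("'cells' (%s) and image (%s) shapes differ",
          paste(dim(cells), collapse = "x"),
          paste(dim(img$intensities), collapse = "x"))
  px <- img$pixel_size_um
  bp <- bandpass_filter(img, params$bandpass_sigma_small_um,
                        params$bandpass_sigma_large_um)
  th <- auto_threshold(bp$intensities, params)
  mask <- bp$intensities > th
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- matrix(as.integer(round(as.matrix(labels))), nrow(mask), ncol(mask))
  labels <- drop_small(labels, params$min_object_area_um2 / px^2)
  if (params$split_enabled)
    labels <- split_touching(labels, params$hmax_prominence_um, px)
  labels[cells <= 0] <- 0L
  relabel_map(labels)
}

#' Per-label mean fluorescence intensity
#'
#' @param img a [calibrated_image()].
#' @param labels integer label matrix of the same shape.
#' @return A data frame with one row per label present in the map: `label`,
#'   `n_pixels`, `mean_intensity` (MFI), `total_intensity`.
#' @export
measure_mfi <- function(img, labels) {
  img <- as_calibrated_image(img)
  if (!all(dim(labels) == dim(img$intensities)))
    stopf("'labels' and image shapes differ")
  fg <- labels > 0
  if (!any(fg))
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      mean_intensity = numeric(0), total_intensity = numeric(0)))
  lab <- labels[fg]
  val <- img$intensities[fg]
  tot <- tapply(val, lab, sum)
  n <- tapply(val, lab, length)
  data.frame(label = as.integer(names(tot)),
             n_pixels = as.integer(n),
             mean_intensity = as.numeric(tot / n),
             total_intensity = as.numeric(tot),
             row.names = NULL)
}
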