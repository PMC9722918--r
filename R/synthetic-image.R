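#' Specification for a synthetic mitochondrial image
#'
#' Describes a single-channel confocal-like image of one or more cells whose
#' mitochondria are drawn as capsules (straight tubes with semicircular caps,
#' optionally mildly bent). Tube length is drawn from three classes matching
#' the fission/fusion scoring convention: short (< 1 um), mid (1-3 um) and
#' long (> 3 um). The forward model is: anti-aliased rasterisation, Gaussian
#' point-spread blur, then additive Gaussian read noise.
#'
#' @param image_size integer `(rows, cols)` in pixels.
#' @param pixel_size_um micrometres per pixel (> 0). Default 0.1 um/px, a
#'   plausible sampling for a 63x oil-immersion objective.
#' @param n_cells number of cells laid out on a jittered grid.
#' @param mito_per_cell number of mitochondria per cell.
#' @param length_mix numeric length-3 vector of class fractions
#'   (short, mid, long); must be in `[0, 1]` and sum to 1 within 1e-9.
#' @param mito_width_um tube width (diameter), in um.
#' @param intensity_fg,intensity_bg mean foreground (mitochondrion) and
#'   background intensity, photon-scale arbitrary units.
#' @param noise_sd standard deviation of additive Gaussian read noise (>= 0).
#' @param psf_sigma_um Gaussian point-spread sigma, um (>= 0; 0 disables blur).
#' @param cell_radius_um radius of the circular cell body, um (default 5,
#'   the scale of a dendritic-cell body at this sampling; fusion-heavy
#'   cells need this much room for several >3 um tubes).
#' @param cytoplasm_frac dim cytoplasm level as a fraction of the
#'   foreground-background contrast; gives cell masks a recoverable footprint.
#' @param bend_max_frac maximal quadratic-Bezier control-point offset as a
#'   fraction of tube length (0 = straight tubes with exact analytic truth).
#' @param allow_touching if `FALSE` (default), tubes are placed with a
#'   clearance of at least `2 * psf_sigma_um` (and two pixels) between their
#'   surfaces, so ground-truth objects remain resolvable.
#' @param seed RNG seed; identical specs with identical seeds produce
#'   bit-identical images and truths.
#' @return An object of class `synthetic_image_spec`.
#' @seealso [generate_mito_image()]
#' @export
synthetic_image_spec <- function(image_size = c(192L, 192L),
                                 pixel_size_um = 0.1,
                                 n_cells = 1L,
                                 mito_per_cell = 6L,
                                 length_mix = c(short = 0.3, mid = 0.4, long = 0.3),
                                 mito_width_um = 0.4,
                                 intensity_fg = 180,
                                 intensity_bg = 8,
                                 noise_sd = 2,
                                 psf_sigma_um = 0.1,
                                 cell_radius_um = 5,
                                 cytoplasm_frac = 0.15,
                                 bend_max_frac = 0,
                                 allow_touching = FALSE,
                                 seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 8))
    stopf("'image_size' must be two pixel dimensions >= 8")
  if (!is_number(pixel_size_um) || pixel_size_um <= 0)
    stopf("'pixel_size_um' must be > 0")
  if (!is_count(n_cells)) stopf("'n_cells' must be a non-negative count")
  if (!is_count(mito_per_cell)) stopf("'mito_per_cell' must be a count")
  if (length(length_mix) != 3L || any(length_mix < 0) || any(length_mix > 1))
    stopf("'length_mix' must be three fractions in [0, 1]")
  if (abs(sum(length_mix) - 1) > 1e-9)
    stopf("'length_mix' must sum to 1 (got %.12g)", sum(length_mix))
  if (!is_number(mito_width_um) || mito_width_um <= 0 || mito_width_um >= 0.8)
    stopf("'mito_width_um' must be in (0, 0.8) so short tubes stay below 1 um")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is_number(psf_sigma_um) || psf_sigma_um < 0)
    stopf("'psf_sigma_um' must be >= 0")
  if (!is_number(cell_radius_um) || cell_radius_um <= 0)
    stopf("'cell_radius_um' must be > 0")
  if (!is_number(bend_max_frac) || bend_max_frac < 0 || bend_max_frac > 0.3)
    stopf("'bend_max_frac' must be in [0, 0.3]")
  structure(
    list(image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
         n_cells = as.integer(n_cells), mito_per_cell = as.integer(mito_per_cell),
         length_mix = unname(as.numeric(length_mix)),
         mito_width_um = mito_width_um,
         intensity_fg = intensity_fg, intensity_bg = intensity_bg,
         noise_sd = noise_sd, psf_sigma_um = psf_sigma_um,
         cell_radius_um = cell_radius_um, cytoplasm_frac = cytoplasm_frac,
         bend_max_frac = bend_max_frac,
         allow_touching = isTRUE(allow_touching), seed = as.integer(seed)),
    class = "synthetic_image_spec")
}

# clearance between neighbouring cell discs: scales with the cell radius so
# that packed fields stay separable after mask smoothing
cell_gap_px <- function(spec) {
  px <- spec$pixel_size_um
  max(4 * spec$psf_sigma_um / px, 0.5 * spec$cell_radius_um / px, 6)
}

# distance from pixel centres (yy, xx) to a polyline given as a 2-column
# matrix of (y, x) vertices; vectorised over pixels, looped over segments
dist_to_polyline <- function(yy, xx, pts) {
  d <- rep(Inf, length(yy))
  for (i in seq_len(nrow(pts) - 1L)) {
    ay <- pts[i, 1]; ax <- pts[i, 2]
    by <- pts[i + 1L, 1]; bx <- pts[i + 1L, 2]
    vy <- by - ay; vx <- bx - ax
    len2 <- vy * vy + vx * vx
    tt <- if (len2 == 0) rep(0, length(yy))
          else pmin(1, pmax(0, ((yy - ay) * vy + (xx - ax) * vx) / len2))
    d <- pmin(d, sqrt((yy - (ay + tt * vy))^2 + (xx - (ax + tt * vx))^2))
  }
  d
}

# minimal distance between two polylines, by dense point sampling
polyline_gap <- function(p1, p2) {
  dens <- function(p) {
    out <- lapply(seq_len(nrow(p) - 1L), function(i) {
      tt <- seq(0, 1, length.out = 8L)
      cbind(p[i, 1] + tt * (p[i + 1L, 1] - p[i, 1]),
            p[i, 2] + tt * (p[i + 1L, 2] - p[i, 2]))
    })
    do.call(rbind, out)
  }
  a <- dens(p1); b <- dens(p2)
  min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
}

# centreline vertices for one tube: straight segment or quadratic Bezier
tube_centreline <- function(center, half_len, theta, bend_offset) {
  u <- c(cos(theta), sin(theta))          # (y, x) direction
  p0 <- center - half_len * u
  p2 <- center + half_len * u
  if (bend_offset == 0) return(rbind(p0, p2))
  nrm <- c(-u[2], u[1])
  pc <- center + bend_offset * nrm
  tt <- seq(0, 1, length.out = 17L)
  cbind((1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * pc[1] + tt^2 * p2[1],
        (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * pc[2] + tt^2 * p2[2])
}

polyline_length <- function(pts)
  sum(sqrt(rowSums(diff(pts)^2)))

# draw one true end-to-end length (um) for a given class; tube width w
draw_class_length <- function(class, w) {
  switch(class,
         short = runif(1, w + 0.12, 0.95),
         mid   = runif(1, 1.0, 3.0),
         long  = runif(1, 3.05, 4.2))
}

#' Generate a synthetic mitochondrial image with exact ground truth
#'
#' Draws each mitochondrion as an anti-aliased capsule of known centreline
#' length and width inside its owning cell, applies a Gaussian point-spread
#' blur and additive Gaussian noise, and returns both the image and the exact
#' per-object truth (label maps, lengths, areas). Ground-truth "length" is
#' the end-to-end extent: centreline length plus tube width, matching the
#' major-axis length convention used by [measure_objects()].
#'
#' @param spec a [synthetic_image_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{image}{[calibrated_image()] — blurred, noisy intensities.}
#'   \item{truth}{list with `cell_labels` and `mito_labels` (integer label
#'     matrices, 0 = background) and `objects`, a data frame with columns
#'     `object_id`, `cell_id`, `length_um`, `area_um2`, `class`.}
#'   \item{spec}{the input spec, echoed.}
#' }
#' @examples
#' out <- generate_mito_image(synthetic_image_spec(n_cells = 1,
#'   mito_per_cell = 5, noise_sd = 0, seed = 7))
#' nrow(out$truth$objects)  # 5
#' @export
generate_mito_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  local_seed(spec$seed, generate_mito_image_impl(spec))
}

generate_mito_image_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  px <- spec$pixel_size_um
  r_px <- spec$cell_radius_um / px
  gap_px <- cell_gap_px(spec)

  canvas <- matrix(spec$intensity_bg, H, W)
  cell_labels <- matrix(0L, H, W)
  mito_labels <- matrix(0L, H, W)
  mito_alpha <- matrix(0, H, W)

  # jittered grid of cell centres
  if (spec$n_cells > 0) {
    ncol_g <- ceiling(sqrt(spec$n_cells))
    nrow_g <- ceiling(spec$n_cells / ncol_g)
    pitch <- 2 * r_px + gap_px
    need_h <- nrow_g * pitch; need_w <- ncol_g * pitch
    if (need_h > H || need_w > W)
      stopf("image %dx%d px too small for %d cells of radius %.3g um (need >= %.0fx%.0f px)",
            H, W, spec$n_cells, spec$cell_radius_um, need_h, need_w)
    off_y <- (H - need_h) / 2; off_x <- (W - need_w) / 2
    centers <- t(vapply(seq_len(spec$n_cells) - 1L, function(k) {
      gy <- k %/% ncol_g; gx <- k %% ncol_g
      c(off_y + (gy + 0.5) * pitch + runif(1, -2, 2),
        off_x + (gx + 0.5) * pitch + runif(1, -2, 2))
    }, numeric(2)))
  } else {
    centers <- matrix(numeric(0), 0, 2)
  }

  cyto_level <- spec$intensity_bg +
    spec$cytoplasm_frac * (spec$intensity_fg - spec$intensity_bg)

  objects <- list()
  obj_id <- 0L
  classes <- c("short", "mid", "long")
  w_um <- spec$mito_width_um
  rad_px <- w_um / 2 / px
  sep_px <- (w_um + max(2 * spec$psf_sigma_um, 2 * px)) / px

  for (ci in seq_len(spec$n_cells)) {
    cc <- centers[ci, ]
    # rasterise the cell disc (anti-aliased cytoplasm, hard label)
    ys <- max(1, floor(cc[1] - r_px - 2)):min(H, ceiling(cc[1] + r_px + 2))
    xs <- max(1, floor(cc[2] - r_px - 2)):min(W, ceiling(cc[2] + r_px + 2))
    gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
    d <- sqrt((gy - cc[1])^2 + (gx - cc[2])^2)
    a <- pmin(1, pmax(0, r_px - d + 0.5))
    idx <- cbind(gy, gx)
    canvas[idx] <- canvas[idx] + a * (cyto_level - canvas[idx])
    cell_labels[idx[d <= r_px, , drop = FALSE]] <- ci

    # draw every class and length for this cell up front so the realised
    # class mix is exactly the multinomial draw, then place longest-first:
    # long tubes need central positions, shorts fill the remaining space
    cls_draw <- classes[sample.int(3L, spec$mito_per_cell, replace = TRUE,
                                   prob = spec$length_mix)]
    len_draw <- vapply(cls_draw, function(cl) draw_class_length(cl, w_um),
                       numeric(1))
    placed <- list()   # centrelines of tubes already in this cell, px units
    for (mi in order(len_draw, decreasing = TRUE)) {
      cls <- cls_draw[mi]
      L_true <- len_draw[mi]                                 # end-to-end, um
      half_ext <- L_true / 2 / px                            # px
      max_rho <- r_px - half_ext - 1.5
      if (max_rho < 0)
        stopf("placement failure: a %.2f um tube does not fit in cell %d (radius %.2f um)",
              L_true, ci, spec$cell_radius_um)
      ok <- FALSE
      for (try in seq_len(1500L)) {
        theta <- runif(1, 0, 2 * pi)
        phi <- runif(1, 0, 2 * pi)
        rho <- sqrt(runif(1)) * max_rho
        center <- cc + rho * c(cos(phi), sin(phi))
        bend <- if (spec$bend_max_frac > 0)
          runif(1, -1, 1) * spec$bend_max_frac * (L_true / px) else 0
        half_len <- (L_true - w_um) / 2 / px                 # centreline half
        pts <- tube_centreline(center, half_len, theta, bend)
        if (!spec$allow_touching && length(placed) > 0) {
          gaps <- vapply(placed, function(p) polyline_gap(p, pts), numeric(1))
          if (min(gaps) < sep_px) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stopf("placement failure: could not place a %.2f um mitochondrion in cell %d without overlap",
              L_true, ci)
      placed[[length(placed) + 1L]] <- pts
      obj_id <- obj_id + 1L

      ext <- rad_px + 2
      ys <- max(1, floor(min(pts[, 1]) - ext)):min(H, ceiling(max(pts[, 1]) + ext))
      xs <- max(1, floor(min(pts[, 2]) - ext)):min(W, ceiling(max(pts[, 2]) + ext))
      gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
      d <- dist_to_polyline(gy, gx, pts)
      a <- pmin(1, pmax(0, rad_px - d + 0.5))
      idx <- cbind(gy, gx)
      mito_alpha[idx] <- pmax(mito_alpha[idx], a)
      mito_labels[idx[d <= rad_px, , drop = FALSE]] <- obj_id

      cl_len_um <- polyline_length(pts) * px
      objects[[obj_id]] <- data.frame(
        object_id = obj_id, cell_id = ci,
        length_um = cl_len_um + w_um,
        area_um2 = cl_len_um * w_um + pi * (w_um / 2)^2,
        class = cls, stringsAsFactors = FALSE)
    }
  }

  canvas <- canvas + mito_alpha * (spec$intensity_fg - canvas)

  canvas <- gauss_blur(canvas, spec$psf_sigma_um / px)
  if (spec$noise_sd > 0)
    canvas <- canvas + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  canvas <- pmax(canvas, 0)

  truth_objects <- if (obj_id > 0) do.call(rbind, objects)
    else data.frame(object_id = integer(0), cell_id = integer(0),
                    length_um = numeric(0), area_um2 = numeric(0),
                    class = character(0))
  list(image = calibrated_image(canvas, px, bit_depth = "synthetic-float"),
       truth = list(cell_labels = cell_labels, mito_labels = mito_labels,
                    objects = truth_objects),
       spec = spec)
}

#' Write a synthetic image and its ground truth to disk
#'
#' Writes the intensity image and both label maps as 16-bit TIFF, the truth
#' table as CSV, and an echo of the spec as JSON.
#'
#' @param sim result of [generate_mito_image()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return The directory, invisibly.
#' @export
write_synthetic_image <- function(sim, dir, stem = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff16(sim$image, file.path(dir, paste0(stem, "_image.tif")))
  write_tiff16(sim$truth$cell_labels, file.path(dir, paste0(stem, "_cells.tif")))
  write_tiff16(sim$truth$mito_labels, file.path(dir, paste0(stem, "_mito.tif")))
  utils::write.csv(sim$truth$objects,
                   file.path(dir, paste0(stem, "_truth.csv")), row.names = FALSE)
  spec_json <- sim$spec
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, file.path(dir, paste0(stem, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
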