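#' Specification for a simulated rhythmic time series
#'
#' Truth model: `value(t) = M + A * cos(2*pi*(t - Phi)/tau) + eps`,
#' `eps ~ N(0, sigma^2)`, independent across replicates and times. Defaults
#' match the study design the package targets: sampling every 4 h over a
#' 48 h course with 3 replicates per time.
#'
#' @param mesor midline level M.
#' @param amplitude peak distance A from the mesor (>= 0).
#' @param acrophase_h peak time Phi in hours, in `[0, period_h)`.
#' @param period_h period tau in hours (> 0), default 24.
#' @param times_h sampling times in hours (non-empty).
#' @param replicates replicates per time point (>= 1).
#' @param noise_sd Gaussian noise SD sigma (>= 0).
#' @param seed RNG seed.
#' @return An object of class `rhythm_sim_spec`.
#' @export
rhythm_sim_spec <- function(mesor = 10, amplitude = 2, acrophase_h = 6,
                            period_h = 24, times_h = seq(0, 48, by = 4),
                            replicates = 3L, noise_sd = 1, seed = 1L) {
  if (!is_number(amplitude) || amplitude < 0) stopf("'amplitude' must be >= 0")
  if (!is_number(period_h) || period_h <= 0) stopf("'period_h' must be > 0")
  if (length(times_h) == 0 || !all(is.finite(times_h)))
    stopf("'times_h' must be non-empty and finite")
  if (!is_number(acrophase_h) || acrophase_h < 0 || acrophase_h >= period_h)
    stopf("'acrophase_h' must lie in [0, period_h)")
  if (!is_count(replicates) || replicates < 1)
    stopf("'replicates' must be a positive count")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  structure(
    list(mesor = mesor, amplitude = amplitude, acrophase_h = acrophase_h,
         period_h = period_h, times_h = as.numeric(times_h),
         replicates = as.integer(replicates), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "rhythm_sim_spec")
}

#' Generate a cosine time series with known truth
#'
#' @param spec a [rhythm_sim_spec()].
#' @return A data frame with columns `time_h`, `value`, `replicate`, carrying
#'   the generating parameters in `attr(, "truth")`.
#' @examples
#' ts <- generate_timeseries(rhythm_sim_spec(mesor = 10, amplitude = 3,
#'   acrophase_h = 8, noise_sd = 0))
#' ts$value[ts$time_h == 8]  # 13 at the peak
#' @export
generate_timeseries <- function(spec) {
  stopifnot(inherits(spec, "rhythm_sim_spec"))
  local_seed(spec$seed, {
    tt <- rep(spec$times_h, each = spec$replicates)
    rep_id <- rep(seq_len(spec$replicates), times = length(spec$times_h))
    mu <- spec$mesor +
      spec$amplitude * cos(2 * pi * (tt - spec$acrophase_h) / spec$period_h)
    val <- mu + if (spec$noise_sd > 0) rnorm(length(tt), 0, spec$noise_sd)
                else 0
    out <- data.frame(time_h = tt, value = val, replicate = rep_id)
    attr(out, "truth") <- spec
    out
  })
}

#' Specification for a simulated Mito Stress oxygen-consumption trace
#'
#' Four phases in the fixed injection order of the standard Mito Stress test:
#' baseline, post-oligomycin (ATP-synthase inhibition), post-FCCP
#' (uncoupling, maximal respiration), post-rotenone/antimycin A
#' (non-mitochondrial respiration).
#'
#' @param rates numeric length-4 vector of true per-phase rates
#'   `(basal_raw, post_oligomycin, post_fccp, post_rotAA)`, all >= 0.
#' @param measurements_per_phase measurements in each phase (>= 1 each;
#'   recycled to length 4).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @return An object of class `ocr_sim_spec`.
#' @export
ocr_sim_spec <- function(rates = c(100, 40, 160, 20),
                         measurements_per_phase = 3L,
                         noise_sd = 0, seed = 1L) {
  if (length(rates) != 4L || any(!is.finite(rates)) || any(rates < 0))
    stopf("'rates' must be four non-negative per-phase rates")
  m <- rep(as.integer(measurements_per_phase), length.out = 4L)
  if (any(m < 1)) stopf("every phase needs at least 1 measurement")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  structure(
    list(rates = as.numeric(rates), measurements_per_phase = m,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ocr_sim_spec")
}

ocr_phases <- c("baseline", "oligomycin", "fccp", "rot_aa")

#' Generate a Mito Stress-like OCR trace
#'
#' @param spec an [ocr_sim_spec()].
#' @return A data frame of class `ocr_trace` with columns `measurement`
#'   (index), `phase` (factor in injection order) and `ocr`; the injection
#'   indices (first measurement of each phase) are recorded in
#'   `attr(, "injections")` and the generating spec in `attr(, "truth")`.
#' @export
generate_ocr_trace <- function(spec) {
  stopifnot(inherits(spec, "ocr_sim_spec"))
  local_seed(spec$seed, {
    m <- spec$measurements_per_phase
    phase <- factor(rep(ocr_phases, times = m), levels = ocr_phases)
    mu <- rep(spec$rates, times = m)
    val <- mu + if (spec$noise_sd > 0) rnorm(length(mu), 0, spec$noise_sd)
                else 0
    out <- data.frame(measurement = seq_along(mu), phase = phase, ocr = val)
    class(out) <- c("ocr_trace", "data.frame")
    attr(out, "injections") <- stats::setNames(cumsum(c(1, m[-4])), ocr_phases)
    attr(out, "truth") <- spec
    out
  })
}

#' Simulate a mitochondrial-morphology time course with a planted rhythm
#'
#' Generates one synthetic multi-cell image per time point with the
#' short-length (fission) class fraction oscillating as
#' `short(t) = mesor + amplitude * cos(2*pi*(t - acrophase_h)/24)`, clipped
#' to `[0.05, 0.9]`; the remainder is split 60/40 between the mid and long
#' classes. With `amplitude = 0` the course is flat (null scenario).
#'
#' @param times_h sampling times in hours.
#' @param cells_per_time cells per time point (one image per time point).
#' @param short_mesor,short_amplitude,short_acrophase_h planted parameters of
#'   the short-fraction oscillation.
#' @param base_spec a [synthetic_image_spec()] supplying all image parameters
#'   except `n_cells`, `length_mix`, `image_size` and `seed`, which are set
#'   here.
#' @param seed RNG seed; per-time-point seeds are derived from it.
#' @return A list with one element per time point: `time_h`, `image`,
#'   `truth` (as in [generate_mito_image()]).
#' @export
simulate_timecourse <- function(times_h = seq(0, 48, by = 12),
                                cells_per_time = 20L,
                                short_mesor = 0.45,
                                short_amplitude = 0.25,
                                short_acrophase_h = 12,
                                base_spec = synthetic_image_spec(),
                                seed = 1L) {
  stopifnot(inherits(base_spec, "synthetic_image_spec"))
  px <- base_spec$pixel_size_um
  r_px <- base_spec$cell_radius_um / px
  gap_px <- cell_gap_px(base_spec)
  ncol_g <- ceiling(sqrt(cells_per_time))
  nrow_g <- ceiling(cells_per_time / ncol_g)
  pitch <- 2 * r_px + gap_px
  size <- c(ceiling(nrow_g * pitch) + 4L, ceiling(ncol_g * pitch) + 4L)

  lapply(seq_along(times_h), function(i) {
    t <- times_h[i]
    short <- short_mesor +
      short_amplitude * cos(2 * pi * (t - short_acrophase_h) / 24)
    short <- min(0.9, max(0.05, short))
    mix <- c(short, 0.6 * (1 - short), 0.4 * (1 - short))
    sp <- base_spec
    sp$n_cells <- as.integer(cells_per_time)
    sp$length_mix <- mix
    sp$image_size <- as.integer(size)
    sp$seed <- as.integer((seed %% 2000000L) * 1000L + i)
    out <- generate_mito_image(sp)
    list(time_h = t, image = out$image, truth = out$truth)
  })
}
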