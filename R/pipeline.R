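run_config_keys <- c("pixel_size_um", "input_dir", "manifest", "segmentation",
                     "period_h", "method", "alpha", "output_dir", "seed",
                     "log_level", "aggregate_by")

#' Construct a time-course run configuration
#'
#' @param pixel_size_um micrometres per pixel; required, never guessed.
#' @param input_dir directory holding one sub-directory per time point named
#'   `t<hours>` (e.g. `t12`), each containing single-channel TIFFs.
#' @param manifest path to a CSV with columns `path`, `time_h` (or a data
#'   frame); takes precedence over `input_dir` when both are given.
#' @param segmentation a [segmentation_params()] or a named list of its
#'   arguments.
#' @param period_h rhythm period (default 24).
#' @param method rhythm method: `"cosinor"` (default), `"jtk"` or `"both"`.
#' @param alpha significance level in `(0, 1)` (default 0.05).
#' @param output_dir optional directory for [write_timecourse_report()].
#' @param seed RNG seed recorded in the provenance block.
#' @param log_level `"info"` or `"quiet"`.
#' @param aggregate_by statistical unit for the rhythm fits: `"cell"`
#'   (default: one observation per cell and time point) or `"object"`
#'   (mitochondria pooled across cells first).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size_um, input_dir = NULL, manifest = NULL,
                       segmentation = segmentation_params(), period_h = 24,
                       method = c("cosinor", "jtk", "both"), alpha = 0.05,
                       output_dir = NULL, seed = 1L,
                       log_level = c("info", "quiet"),
                       aggregate_by = c("cell", "object")) {
  if (missing(pixel_size_um) || !is_number(pixel_size_um) || pixel_size_um <= 0)
    stopf("'pixel_size_um' is required and must be > 0 (it is never guessed)")
  method <- match.arg(method)
  log_level <- match.arg(log_level)
  aggregate_by <- match.arg(aggregate_by)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must be in (0, 1)")
  if (is.list(segmentation) && !inherits(segmentation, "segmentation_params"))
    segmentation <- do.call(segmentation_params, segmentation)
  structure(
    list(pixel_size_um = pixel_size_um, input_dir = input_dir,
         manifest = manifest, segmentation = segmentation,
         period_h = period_h, method = method, alpha = alpha,
         output_dir = output_dir, seed = as.integer(seed),
         log_level = log_level, aggregate_by = aggregate_by),
    class = "run_config")
}

nearest_key <- function(key, valid) {
  d <- utils::adist(key, valid, ignore.case = TRUE)
  valid[which.min(d)]
}

#' Parse and validate a YAML run configuration
#'
#' Unknown keys are rejected with a suggestion of the nearest valid key;
#' `pixel_size_um` is mandatory.
#'
#' @param path path to a YAML file.
#' @return A [run_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stopf("unknown config key '%s'; did you mean '%s'?",
          unknown[1], nearest_key(unknown[1], run_config_keys))
  if (!is.null(cfg$segmentation)) {
    seg_keys <- names(formals(segmentation_params))
    bad <- setdiff(names(cfg$segmentation), seg_keys)
    if (length(bad))
      stopf("unknown segmentation key '%s'; did you mean '%s'?",
            bad[1], nearest_key(bad[1], seg_keys))
  }
  do.call(run_config, cfg)
}

log_msg <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(fmt, ...))
}

# resolve the image list for a run: in-memory images win, then manifest,
# then t<hours> directory scan
collect_images <- function(config, images) {
  if (!is.null(images)) return(images)
  entries <- NULL
  if (!is.null(config$manifest)) {
    man <- if (is.data.frame(config$manifest)) config$manifest
           else utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "time_h") %in% names(man)))
      stopf("manifest needs columns 'path' and 'time_h'")
    entries <- man
  } else if (!is.null(config$input_dir)) {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    tdirs <- dirs[grepl("^t[0-9]+(\\.[0-9]+)?$", basename(dirs))]
    if (length(tdirs) == 0)
      stopf("no t<hours> sub-directories found under %s", config$input_dir)
    entries <- do.call(rbind, lapply(tdirs, function(d) {
      tifs <- list.files(d, pattern = "\\.tiff?$", full.names = TRUE)
      if (length(tifs) == 0) return(NULL)
      data.frame(path = tifs,
                 time_h = as.numeric(sub("^t", "", basename(d))))
    }))
  } else stopf("config needs 'manifest' or 'input_dir' (or pass images=)")
  if (is.null(entries) || nrow(entries) == 0)
    stopf("no input images found")
  lapply(seq_len(nrow(entries)), function(i)
    list(time_h = entries$time_h[i], path = entries$path[i]))
}

analyse_one_image <- function(entry, config, image_id) {
  img <- if (!is.null(entry$image)) entry$image
         else read_calibrated_tiff(entry$path, config$pixel_size_um)
  cells <- segment_cells(img, config$segmentation)
  mito <- segment_mitochondria(img, config$segmentation, cells)
  recs <- measure_objects(mito, img, cells)
  cell_ids <- sort(unique(cells[cells > 0]))
  summ <- summarize_cells(recs, all_cell_ids = cell_ids)

  # per-cell MFI over each cell's mitochondrial pixels
  mfi_obj <- measure_mfi(img, mito)
  cell_of <- stats::setNames(recs$cell_id, recs$object_id)
  mfi_cell <- rep(NA_real_, nrow(summ))
  if (nrow(mfi_obj)) {
    own <- cell_of[as.character(mfi_obj$label)]
    tot <- tapply(mfi_obj$total_intensity, own, sum)
    npx <- tapply(mfi_obj$n_pixels, own, sum)
    m <- tot / npx
    mfi_cell <- as.numeric(m[as.character(summ$cell_id)])
  }
  data.frame(image_id = image_id, time_h = entry$time_h,
             cell_id = summ$cell_id, n_mito = summ$n_mito,
             fission_fraction = summ$frac_short,
             fusion_fraction = summ$frac_long,
             median_length_um = summ$median_length_um,
             mfi = mfi_cell)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

timecourse_metrics <- c("fission_fraction", "fusion_fraction",
                        "median_length_um", "mfi")

#' Run the image-to-rhythm morphology time course
#'
#' For every input image: cell segmentation, mitochondrial segmentation,
#' per-object morphology, per-cell summaries and mitochondrial MFI. Per-cell
#' values are aggregated per time point (mean +/- SEM over cells) and, when
#' at least 4 time points are available, each of the four study metrics
#' (fission fraction, fusion fraction, median length, MFI) is tested for
#' rhythmicity with the configured method. Unreadable images are recorded as
#' per-file errors and the run continues. The result is fully deterministic
#' given config and inputs.
#'
#' @param config a [run_config()].
#' @param images optional in-memory input: a list of `list(time_h=, image=)`
#'   entries (as produced by [simulate_timecourse()]), bypassing file IO.
#' @return An object of class `timecourse_report`: `per_cell`,
#'   `per_timepoint`, `rhythm` (per metric: the cosinor and/or JTK results
#'   and a `rhythmic` flag), `errors` (data frame of failed inputs),
#'   `config` and a `provenance` block.
#' @export
run_morphology_timecourse <- function(config, images = NULL) {
  stopifnot(inherits(config, "run_config"))
  entries <- collect_images(config, images)
  per_cell <- list(); errors <- list()
  for (i in seq_along(entries)) {
    res <- tryCatch(analyse_one_image(entries[[i]], config, i),
                    error = function(e)
                      data.frame(image_id = i,
                                 time_h = entries[[i]]$time_h,
                                 error = conditionMessage(e)))
    if ("error" %in% names(res)) errors[[length(errors) + 1L]] <- res
    else {
      per_cell[[length(per_cell) + 1L]] <- res
      log_msg(config, "image %d (t=%g h): %d cells, %d mitochondria",
              i, entries[[i]]$time_h, nrow(res), sum(res$n_mito))
    }
  }
  per_cell <- if (length(per_cell)) do.call(rbind, per_cell)
              else stopf("no image could be analysed")
  errors <- if (length(errors)) do.call(rbind, errors)
            else data.frame(image_id = integer(0), time_h = numeric(0),
                            error = character(0))

  tps <- sort(unique(per_cell$time_h))
  per_tp <- do.call(rbind, lapply(tps, function(tp) {
    d <- per_cell[per_cell$time_h == tp, , drop = FALSE]
    row <- data.frame(time_h = tp, n_cells = nrow(d))
    for (m in timecourse_metrics) {
      row[[paste0("mean_", m)]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0("sem_", m)]] <- sem(d[[m]])
    }
    row
  }))

  rhythm <- NULL
  if (length(tps) >= 4) {
    rhythm <- lapply(timecourse_metrics, function(m) {
      d <- per_cell[is.finite(per_cell[[m]]), c("time_h", m)]
      names(d) <- c("time_h", "value")
      out <- list(metric = m, cosinor = NULL, jtk = NULL, rhythmic = NA)
      if (config$method %in% c("cosinor", "both"))
        out$cosinor <- fit_cosinor(d, period_h = config$period_h)
      if (config$method %in% c("jtk", "both"))
        out$jtk <- jtk_test(d, period_h = config$period_h)
      p <- if (config$method == "jtk") out$jtk$p_adjusted
           else out$cosinor$p_zero_amplitude
      out$rhythmic <- is.finite(p) && p < config$alpha
      out
    })
    names(rhythm) <- timecourse_metrics
  } else {
    warning(sprintf("only %d time point(s); rhythm stage skipped (needs >= 4)",
                    length(tps)), call. = FALSE)
  }

  cfg_plain <- config
  cfg_plain$segmentation <- unclass(cfg_plain$segmentation)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg_plain), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  structure(
    list(per_cell = per_cell, per_timepoint = per_tp, rhythm = rhythm,
         errors = errors, config = config,
         provenance = list(config_hash = cfg_hash, seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("mitorhythm")))),
    class = "timecourse_report")
}

#' @export
print.timecourse_report <- function(x, ...) {
  cat(sprintf("Time-course report: %d time points, %d cells, %d error(s)\n",
              nrow(x$per_timepoint), nrow(x$per_cell), nrow(x$errors)))
  if (!is.null(x$rhythm)) {
    for (m in names(x$rhythm)) {
      r <- x$rhythm[[m]]
      p <- if (!is.null(r$cosinor)) r$cosinor$p_zero_amplitude
           else r$jtk$p_adjusted
      cat(sprintf("  %-18s p = %-10.3g rhythmic: %s\n", m, p, r$rhythmic))
    }
  } else cat("  rhythm stage skipped\n")
  invisible(x)
}

#' Write a time-course report to disk
#'
#' Per-cell and per-timepoint tables as CSV, and the rhythm results plus
#' provenance as JSON.
#'
#' @param report a `timecourse_report`.
#' @param dir output directory (created if needed); defaults to the
#'   configured `output_dir`.
#' @return The directory, invisibly.
#' @export
write_timecourse_report <- function(report, dir = report$config$output_dir) {
  if (is.null(dir)) stopf("no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_cell, file.path(dir, "per_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_timepoint, file.path(dir, "per_timepoint.csv"),
                   row.names = FALSE)
  utils::write.csv(report$errors, file.path(dir, "errors.csv"),
                   row.names = FALSE)
  rj <- lapply(report$rhythm, function(r) {
    out <- list(metric = r$metric, rhythmic = r$rhythmic)
    if (!is.null(r$cosinor))
      out$cosinor <- r$cosinor[c("period_h", "mesor", "beta", "gamma",
                                 "amplitude", "acrophase_h",
                                 "p_zero_amplitude", "n")]
    if (!is.null(r$jtk))
      out$jtk <- r$jtk[c("period_h", "best_phase_h", "tau", "p_adjusted", "n")]
    out
  })
  jsonlite::write_json(list(rhythm = rj, provenance = report$provenance),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
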