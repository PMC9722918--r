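#' Mito Stress respiration parameters from an OCR trace
#'
#' Standard extracellular-flux derivation: non-mitochondrial respiration is
#' the mean of the post-rotenone/antimycin-A phase and is subtracted from the
#' raw rates; basal respiration uses the last (equilibrated) baseline
#' measurement by default; maximal respiration is the highest post-FCCP
#' measurement; spare respiratory capacity is `maximal - basal` and is also
#' reported as `100 * maximal / basal` percent. A negative corrected basal or
#' maximal rate is returned as-is with a quality warning flag, never clamped.
#'
#' @param trace an `ocr_trace` from [generate_ocr_trace()], or any data frame
#'   with columns `phase` (values `baseline`, `oligomycin`, `fccp`, `rot_aa`)
#'   and `ocr`.
#' @param basal_stat `"last"` (default) or `"mean"` of the baseline phase.
#' @return An object of class `mito_stress_params`: `non_mito`, `basal`,
#'   `maximal`, `spare_capacity`, `src_percent`, `quality_warning`.
#' @examples
#' tr <- generate_ocr_trace(ocr_sim_spec(rates = c(100, 40, 160, 20)))
#' mito_stress_params(tr)  # non-mito 20, basal 80, maximal 140, spare 60
#' @export
mito_stress_params <- function(trace, basal_stat = c("last", "mean")) {
  basal_stat <- match.arg(basal_stat)
  if (!is.data.frame(trace) || !all(c("phase", "ocr") %in% names(trace)))
    stopf("'trace' must be a data frame with columns 'phase' and 'ocr'")
  ph <- as.character(trace$phase)
  missing <- setdiff(ocr_phases, unique(ph))
  if (length(missing))
    stopf("trace is missing phase(s): %s", paste(missing, collapse = ", "))
  # phases must appear in injection order
  first_idx <- vapply(ocr_phases, function(p) min(which(ph == p)), numeric(1))
  if (is.unsorted(first_idx, strictly = TRUE))
    stopf("phases must appear in the order %s", paste(ocr_phases, collapse = " -> "))

  non_mito <- mean(trace$ocr[ph == "rot_aa"])
  base_vals <- trace$ocr[ph == "baseline"]
  basal_raw <- if (basal_stat == "last") base_vals[length(base_vals)]
               else mean(base_vals)
  basal <- basal_raw - non_mito
  maximal <- max(trace$ocr[ph == "fccp"]) - non_mito
  out <- list(non_mito = non_mito, basal = basal, maximal = maximal,
              spare_capacity = maximal - basal,
              src_percent = if (basal > 0) 100 * maximal / basal else NA_real_,
              quality_warning = basal < 0 || maximal < 0)
  class(out) <- "mito_stress_params"
  out
}

#' @export
print.mito_stress_params <- function(x, ...) {
  cat(sprintf(paste0("Mito Stress parameters\n  non-mitochondrial %.4g\n",
                     "  basal %.4g\n  maximal %.4g\n  spare capacity %.4g",
                     " (%.4g%% of basal)\n"),
              x$non_mito, x$basal, x$maximal, x$spare_capacity, x$src_percent))
  if (x$quality_warning) cat("  warning: negative corrected rate\n")
  invisible(x)
}

#' Delta-delta-Ct fold changes
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' dCt of the control condition (per target gene); fold change is
#' `2^(-ddCt)`. Fold changes are invariant to uniform Ct shifts, and the
#' control condition's fold changes geometric-mean to 1 by construction.
#'
#' @param ct data frame with columns `sample`, `condition`, `gene`,
#'   `is_reference` (logical; exactly one reference Ct per sample) and `ct`.
#' @param control_condition name of the control condition.
#' @return A data frame with one row per (sample, target gene): `sample`,
#'   `condition`, `gene`, `dct`, `ddct`, `fold_change`.
#' @examples
#' ct <- data.frame(
#'   sample = c("t1", "t1", "c1", "c1"),
#'   condition = c("treated", "treated", "control", "control"),
#'   gene = c("TargetA", "18s", "TargetA", "18s"),
#'   is_reference = c(FALSE, TRUE, FALSE, TRUE),
#'   ct = c(20, 15, 22, 15))
#' ddct_fold_change(ct, "control")$fold_change  # 4, 1
#' @export
ddct_fold_change <- function(ct, control_condition) {
  need <- c("sample", "condition", "gene", "is_reference", "ct")
  if (!all(need %in% names(ct)))
    stopf("'ct' needs columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct))) stopf("all Ct values must be finite")
  if (!control_condition %in% ct$condition)
    stopf("control condition '%s' not present", control_condition)

  refs <- ct[ct$is_reference, , drop = FALSE]
  ref_ct <- tapply(refs$ct, refs$sample, mean)
  targets <- ct[!ct$is_reference, , drop = FALSE]
  no_ref <- setdiff(unique(targets$sample), names(ref_ct))
  if (length(no_ref))
    stopf("missing reference-gene Ct for sample(s): %s",
          paste(no_ref, collapse = ", "))

  targets$dct <- targets$ct - as.numeric(ref_ct[targets$sample])
  ctrl <- targets[targets$condition == control_condition, , drop = FALSE]
  ctrl_mean <- tapply(ctrl$dct, ctrl$gene, mean)
  no_ctrl <- setdiff(unique(targets$gene), names(ctrl_mean))
  if (length(no_ctrl))
    stopf("no control-condition Ct for gene(s): %s",
          paste(no_ctrl, collapse = ", "))
  targets$ddct <- targets$dct - as.numeric(ctrl_mean[targets$gene])
  targets$fold_change <- 2^(-targets$ddct)
  rownames(targets) <- NULL
  targets[, c("sample", "condition", "gene", "dct", "ddct", "fold_change")]
}
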