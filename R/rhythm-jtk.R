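# Kendall machinery for the JTK-style rhythm test.
#
# S = sum_{i<j} sign(x_j - x_i) * sign(y_j - y_i); tau-b normalises by the
# tie-corrected pair counts. The null distribution of S is computed exactly
# (inversion-count recursion) when n <= 9 and neither ranking has ties, and
# by the tie-corrected normal approximation otherwise.

kendall_S <- function(x, y) {
  sum(sign(outer(x, x, "-")) * sign(outer(y, y, "-"))) / 2
}

# tie-group sizes by exact equality (table() would merge near-equal floats
# inconsistently with the sign comparisons above)
tie_sizes <- function(x) as.numeric(table(match(x, unique(x))))

tau_b <- function(x, y, S) {
  n <- length(x)
  n0 <- n * (n - 1) / 2
  tx <- tie_sizes(x); ty <- tie_sizes(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) NA_real_ else S / den
}

# exact null counts of the number of concordant-minus-discordant statistic
# for untied rankings of n items: S takes values -n0, -n0+2, ..., n0 and the
# inversion-count generating function is prod_k (1 + x + ... + x^k)
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b))
    out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  out
}

exact_S_upper_p <- function(S, n) {
  counts <- 1
  for (k in 1:(n - 1)) counts <- polymul(counts, rep(1, k + 1))
  n0 <- n * (n - 1) / 2
  svals <- n0 - 2 * (seq_along(counts) - 1)   # inversions i -> S = n0 - 2i
  sum(counts[svals >= S]) / sum(counts)
}

normal_S_upper_p <- function(S, x, y) {
  n <- length(x)
  tx <- tie_sizes(x); ty <- tie_sizes(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  if (v <= 0) return(1)
  stats::pnorm(S / sqrt(v), lower.tail = FALSE)
}

kendall_upper_p <- function(x, y, S) {
  n <- length(x)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 9 && no_ties) exact_S_upper_p(S, n)
  else normal_S_upper_p(S, x, y)
}

#' JTK-style nonparametric rhythm test at a fixed period
#'
#' For each candidate acrophase on a grid, computes Kendall's tau between the
#' observations and a cosine reference of the given period peaking at that
#' phase, with a one-sided (concordance) p-value from the exact Kendall null
#' when `n <= 9` without ties or from the tie-corrected normal approximation
#' otherwise. The minimum p over phases is Bonferroni-adjusted by the number
#' of phases and capped at 1. This is a single fixed-period variant of the
#' JTK_CYCLE approach (no period scan).
#'
#' @param times numeric times in hours, or a data frame with columns
#'   `time_h` and `value`.
#' @param values measurements (ignored when `times` is a data frame).
#' @param period_h fixed period, default 24.
#' @param phase_step_h spacing of candidate acrophases; defaults to the
#'   sampling interval (smallest positive gap between distinct times).
#' @return An object of class `jtk_result`: `period_h`, `phases` (data frame
#'   `phase_h`, `tau`, `p`), `best_phase_h`, `tau` (at best phase),
#'   `p_adjusted`, `n`, `all_tied` flag.
#' @export
jtk_test <- function(times, values = NULL, period_h = 24, phase_step_h = NULL) {
  ts <- extract_ts(times, values)
  t <- ts$t; y <- ts$y
  n <- length(y)
  if (n < 6) stopf("jtk_test needs at least 6 observations, got %d", n)
  if (is.null(phase_step_h)) {
    gaps <- diff(sort(unique(t)))
    gaps <- gaps[gaps > 1e-9]
    phase_step_h <- if (length(gaps)) min(gaps) else period_h / 6
  }
  phases <- seq(0, period_h - phase_step_h / 2, by = phase_step_h)

  if (length(unique(y)) == 1L) {
    res <- list(period_h = period_h,
                phases = data.frame(phase_h = phases, tau = NA_real_, p = 1),
                best_phase_h = NA_real_, tau = NA_real_, p_adjusted = 1,
                n = n, all_tied = TRUE)
    class(res) <- "jtk_result"
    return(res)
  }

  rows <- lapply(phases, function(ph) {
    # fold times into one period and round the reference so that repeated
    # sampling phases tie exactly and antiphase references negate exactly
    ref <- round(cos(2 * pi * (((t - ph) %% period_h)) / period_h), 9)
    S <- kendall_S(ref, y)
    data.frame(phase_h = ph, tau = tau_b(ref, y, S),
               p = kendall_upper_p(ref, y, S))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$p)
  res <- list(period_h = period_h, phases = tab,
              best_phase_h = tab$phase_h[best], tau = tab$tau[best],
              p_adjusted = min(1, nrow(tab) * min(tab$p)),
              n = n, all_tied = FALSE)
  class(res) <- "jtk_result"
  res
}

#' @export
print.jtk_result <- function(x, ...) {
  cat(sprintf("JTK rhythm test (period %.4g h, n = %d, %d phases)\n",
              x$period_h, x$n, nrow(x$phases)))
  if (x$all_tied) cat("  all values tied; p = 1\n")
  else cat(sprintf("  best phase %.4g h  tau %.3f  adjusted p = %.3g\n",
                   x$best_phase_h, x$tau, x$p_adjusted))
  invisible(x)
}

#' Rhythm screening across many analytes
#'
#' Runs [fit_cosinor()] and/or [jtk_test()] per analyte on a tidy table.
#' Analytes with too few observations are reported with status
#' `"insufficient data"` rather than dropped. Duplicated analyte rows are
#' treated as replicates and pooled.
#'
#' @param table data frame with columns `analyte`, `time_h`, `value`.
#' @param period_h fixed period, default 24.
#' @param method `"cosinor"`, `"jtk"` or `"both"`; the rhythmic flag uses the
#'   cosinor p unless `method = "jtk"`.
#' @param alpha significance level for the rhythmic flag (default 0.05).
#' @param p_adjust `"none"` (default; per-analyte p as reported) or `"BH"`
#'   for Benjamini-Hochberg across analytes.
#' @return A data frame with one row per analyte: `analyte`, `n`, `mesor`,
#'   `amplitude`, `acrophase_h`, `p_cosinor`, `jtk_phase_h`, `tau`, `p_jtk`,
#'   `rhythmic`, `status`.
#' @export
batch_rhythm <- function(table, period_h = 24,
                         method = c("both", "cosinor", "jtk"),
                         alpha = 0.05, p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  need <- c("analyte", "time_h", "value")
  if (!all(need %in% names(table)))
    stopf("'table' needs columns %s", paste(need, collapse = ", "))
  analytes <- unique(table$analyte)
  empty <- data.frame(analyte = character(0), n = integer(0),
                      mesor = numeric(0), amplitude = numeric(0),
                      acrophase_h = numeric(0), p_cosinor = numeric(0),
                      jtk_phase_h = numeric(0), tau = numeric(0),
                      p_jtk = numeric(0), rhythmic = logical(0),
                      status = character(0))
  if (length(analytes) == 0) return(empty)
  rows <- lapply(analytes, function(a) {
    d <- table[table$analyte == a, , drop = FALSE]
    out <- data.frame(analyte = a, n = nrow(d), mesor = NA_real_,
                      amplitude = NA_real_, acrophase_h = NA_real_,
                      p_cosinor = NA_real_, jtk_phase_h = NA_real_,
                      tau = NA_real_, p_jtk = NA_real_,
                      rhythmic = NA, status = "ok",
                      stringsAsFactors = FALSE)
    enough_cos <- nrow(d) >= 4 && length(unique(d$time_h)) >= 3
    enough_jtk <- nrow(d) >= 6
    if (method %in% c("both", "cosinor")) {
      if (enough_cos) {
        f <- fit_cosinor(d$time_h, d$value, period_h)
        out$mesor <- f$mesor; out$amplitude <- f$amplitude
        out$acrophase_h <- f$acrophase_h; out$p_cosinor <- f$p_zero_amplitude
      } else out$status <- "insufficient data"
    }
    if (method %in% c("both", "jtk")) {
      if (enough_jtk) {
        j <- jtk_test(d$time_h, d$value, period_h)
        out$jtk_phase_h <- j$best_phase_h; out$tau <- j$tau
        out$p_jtk <- j$p_adjusted
      } else out$status <- "insufficient data"
    }
    out
  })
  rep <- do.call(rbind, rows)
  pcol <- if (method == "jtk") "p_jtk" else "p_cosinor"
  if (p_adjust == "BH") {
    ok <- !is.na(rep[[pcol]])
    rep[[pcol]][ok] <- stats::p.adjust(rep[[pcol]][ok], method = "BH")
  }
  rep$rhythmic <- !is.na(rep[[pcol]]) & rep[[pcol]] < alpha
  rep$rhythmic[rep$status != "ok"] <- NA
  rep
}
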