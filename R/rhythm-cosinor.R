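#' Acrophase in hours from linearised cosinor coefficients
#'
#' For the model `Y = M + beta*cos(2*pi*t/tau) + gamma*sin(2*pi*t/tau)` the
#' fitted curve equals `M + A*cos(2*pi*(t - Phi)/tau)` with
#' `Phi = atan2(gamma, beta) * tau/(2*pi) mod tau`, so the returned value is
#' the time at which the fitted curve attains its maximum (the full-quadrant
#' form of the textbook `tan^-1(-gamma/beta)` expression).
#'
#' @param beta,gamma cosine and sine coefficients.
#' @param period_h period tau in hours.
#' @return Acrophase in `[0, period_h)`; `NA` when `beta == gamma == 0`
#'   (undefined acrophase of a flat curve).
#' @examples
#' acrophase_hours(2, 0)   # 0: pure cosine peaks at t = 0
#' acrophase_hours(0, 2)   # 6: pure sine peaks at tau/4
#' acrophase_hours(0, -2)  # 18
#' @export
acrophase_hours <- function(beta, gamma, period_h = 24) {
  if (beta == 0 && gamma == 0) return(NA_real_)
  (atan2(gamma, beta) * period_h / (2 * pi)) %% period_h
}

extract_ts <- function(times, values) {
  if (is.data.frame(times)) {
    df <- times
    tcol <- intersect(c("time_h", "time", "t"), names(df))[1]
    vcol <- intersect(c("value", "y"), names(df))[1]
    if (is.na(tcol) || is.na(vcol))
      stopf("data frame input needs 'time_h' and 'value' columns")
    times <- df[[tcol]]; values <- df[[vcol]]
  }
  keep <- is.finite(times) & is.finite(values)
  list(t = as.numeric(times[keep]), y = as.numeric(values[keep]))
}

#' Fit a fixed-period linearised cosinor model
#'
#' Ordinary least squares of
#' `Y_i = M + beta*cos(2*pi*t_i/tau) + gamma*sin(2*pi*t_i/tau)` over all
#' observations (replicates pooled), with amplitude
#' `A = sqrt(beta^2 + gamma^2)`, acrophase from [acrophase_hours()], and a
#' zero-amplitude F test of `H0: beta = gamma = 0`. Sampling designs in which
#' one harmonic term is aliased (for example 12 h sampling of a 24 h
#' rhythm, which cannot identify the sine term) are handled by dropping the
#' aliased column; the test degrees of freedom follow the design rank.
#'
#' @param times numeric times in hours, or a data frame with columns
#'   `time_h` and `value`.
#' @param values measurements (ignored when `times` is a data frame).
#' @param period_h fixed period tau in hours, default 24.
#' @return An object of class `cosinor_fit`: a list with `period_h`,
#'   `mesor`, `beta`, `gamma`, `amplitude`, `acrophase_h`,
#'   `p_zero_amplitude`, `rss` (residual sum of squares), `ss_null`
#'   (intercept-only SS), `n`, `rank`, `fitted`, `residuals`, `times`,
#'   `values`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' y <- 10 + 3 * cos(2 * pi * (t - 8) / 24)
#' fit <- fit_cosinor(t, y)
#' c(fit$mesor, fit$amplitude, fit$acrophase_h)
#' @export
fit_cosinor <- function(times, values = NULL, period_h = 24) {
  ts <- extract_ts(times, values)
  t <- ts$t; y <- ts$y
  n <- length(y)
  if (n < 4) stopf("cosinor fit needs at least 4 observations, got %d", n)
  if (length(unique(t)) < 3)
    stopf("singular design: cosinor fit needs at least 3 distinct times")
  w <- 2 * pi * t / period_h
  X <- cbind(1, cos(w), sin(w))

  if (stats::var(y) == 0) {
    # constant data: flat model with defined degenerate outputs
    fit <- list(period_h = period_h, mesor = y[1], beta = 0, gamma = 0,
                amplitude = 0, acrophase_h = NA_real_, p_zero_amplitude = 1,
                rss = 0, ss_null = 0, n = n, rank = 1L,
                fitted = rep(y[1], n), residuals = rep(0, n),
                times = t, values = y)
    class(fit) <- "cosinor_fit"
    return(fit)
  }

  # drop harmonic columns that are numerically zero at these times (e.g. the
  # sine term under 12 h sampling of a 24 h period): qr() keeps such columns
  # because their reduced norm never falls relative to their own tiny norm
  norms <- sqrt(colSums(X^2))
  keep <- norms > 1e-9 * sqrt(n)
  qx <- qr(X[, keep, drop = FALSE])
  coefs_k <- qr.coef(qx, y)
  coefs_k[is.na(coefs_k)] <- 0    # exactly collinear term -> 0
  coefs <- numeric(3)
  coefs[keep] <- coefs_k
  fitted <- as.numeric(X %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  ss0 <- sum((y - mean(y))^2)
  rank <- qx$rank
  if (rank < 2)
    stopf("singular design: harmonic terms are not estimable at these times")

  amp <- sqrt(coefs[2]^2 + coefs[3]^2)
  fit <- list(period_h = period_h,
              mesor = unname(coefs[1]), beta = unname(coefs[2]),
              gamma = unname(coefs[3]), amplitude = unname(amp),
              acrophase_h = acrophase_hours(coefs[2], coefs[3], period_h),
              p_zero_amplitude = NA_real_,
              rss = rss, ss_null = ss0, n = n, rank = rank,
              fitted = fitted, residuals = res, times = t, values = y)
  class(fit) <- "cosinor_fit"
  fit$p_zero_amplitude <- zero_amplitude_test(fit)
  fit
}

#' F test of zero rhythm amplitude
#'
#' Tests `H0: beta = gamma = 0` by comparing the cosinor fit against the
#' intercept-only model:
#' `F = ((SS0 - SS1)/df1) / (SS1/df2)` with `df1 = rank - 1` harmonic terms
#' and `df2 = n - rank` residual degrees of freedom (`df1 = 2`, `df2 = n - 3`
#' for a fully identified design); p from the F distribution. A perfect fit
#' (`SS1 = 0`) with nonzero amplitude is reported at the underflow floor
#' (p < 1e-15); constant data give p = 1.
#'
#' @param fit a `cosinor_fit` from [fit_cosinor()].
#' @return The p-value.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$amplitude == 0 && fit$rss == fit$ss_null) return(1)
  df1 <- fit$rank - 1L
  df2 <- fit$n - fit$rank
  if (df2 < 1) return(NA_real_)
  if (fit$rss <= 0) return(1e-16)
  f <- ((fit$ss_null - fit$rss) / df1) / (fit$rss / df2)
  max(stats::pf(f, df1, df2, lower.tail = FALSE), 1e-16)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("Cosinor fit (period %.4g h, n = %d)\n", x$period_h, x$n))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %.4g h\n",
              x$mesor, x$amplitude, x$acrophase_h))
  cat(sprintf("  zero-amplitude p = %.3g\n", x$p_zero_amplitude))
  invisible(x)
}
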