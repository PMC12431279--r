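# Align two hr_series onto the finer of their grids over the overlap.
# Edge-affected samples of either series are flagged in the result.
align_series <- function(a, b) {
  stopifnot(inherits(a, "hr_series"), inherits(b, "hr_series"))
  lo <- max(min(a$times), min(b$times))
  hi <- min(max(a$times), max(b$times))
  if (hi <= lo) stop("series have no overlapping time span")
  fs <- max(a$fs_out, b$fs_out, na.rm = TRUE)
  grid <- seq(lo, hi, by = 1 / fs)
  va <- stats::approx(a$times, a$values, xout = grid)$y
  vb <- stats::approx(b$times, b$values, xout = grid)$y
  ea <- stats::approx(a$times, as.numeric(a$edge), xout = grid,
                      method = "constant", rule = 2)$y > 0
  eb <- stats::approx(b$times, as.numeric(b$edge), xout = grid,
                      method = "constant", rule = 2)$y > 0
  list(times = grid, a = va, b = vb, edge = ea | eb)
}

#' Mean and standard deviation of a heart-rate series
#'
#' @param hr An [hr_series()].
#' @return Named numeric vector `c(mean, sd)` in Hz (sample SD, n-1).
#' @export
hr_summary_stats <- function(hr) {
  stopifnot(inherits(hr, "hr_series"))
  v <- hr$values[!hr$gap]
  if (!length(v)) stop("empty series")
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Mean absolute difference between two heart-rate series
#'
#' Both series are linearly resampled to the finer of the two grids over
#' their overlapping span, then the mean absolute pointwise difference is
#' returned.
#'
#' @param a,b Two [hr_series()] with overlapping spans.
#' @return Mean absolute difference in Hz.
#' @export
mean_abs_diff <- function(a, b) {
  al <- align_series(a, b)
  mean(abs(al$a - al$b))
}

#' Bland-Altman agreement analysis of two heart-rate series
#'
#' Computes the pairwise differences `d = a - b` on a common grid and the
#' Bland-Altman statistics: mean difference, 95% limits of agreement
#' `mean(d) +/- 1.96 sd(d)`, confidence intervals for the mean and each
#' limit (standard errors `sd/sqrt(n)` and `sd*sqrt(3/n)` with t quantiles),
#' and the percentage of differences falling outside the limits.
#'
#' @param a,b Two [hr_series()] with overlapping spans and at least 3
#'   aligned points.
#' @param conf Confidence level for the interval estimates (default 0.95).
#' @return Object of class `agreement_report`.
#' @export
bland_altman <- function(a, b, conf = 0.95) {
  al <- align_series(a, b)
  d <- al$a - al$b
  n <- length(d)
  if (n < 3L) stop("need at least 3 aligned points")
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sdd
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  se_mean <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  outside <- 100 * mean(d < loa[1L] | d > loa[2L])
  structure(list(
    mean_a = mean(al$a), mean_b = mean(al$b),
    sd_a = stats::sd(al$a), sd_b = stats::sd(al$b),
    mean_abs_diff = mean(abs(d)),
    ba_mean_diff = md,
    ba_loa_lo = loa[1L], ba_loa_hi = loa[2L],
    ba_ci = list(mean = md + c(-1, 1) * tq * se_mean,
                 loa_lo = loa[1L] + c(-1, 1) * tq * se_loa,
                 loa_hi = loa[2L] + c(-1, 1) * tq * se_loa),
    pct_outside_loa = outside,
    max_rel_discrepancy = {
      keep <- if (any(!al$edge)) !al$edge else rep(TRUE, n)
      100 * max(abs(d[keep]) / al$b[keep])
    },
    n = n, conf = conf),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Bland-Altman agreement report\n")
  cat(sprintf("  n aligned          %d\n", x$n))
  cat(sprintf("  mean (sd) a        %.4f (%.4f) Hz\n", x$mean_a, x$sd_a))
  cat(sprintf("  mean (sd) b        %.4f (%.4f) Hz\n", x$mean_b, x$sd_b))
  cat(sprintf("  mean |a-b|         %.5f Hz\n", x$mean_abs_diff))
  cat(sprintf("  mean diff [CI]     %.5f [%.5f, %.5f] Hz\n", x$ba_mean_diff,
              x$ba_ci$mean[1L], x$ba_ci$mean[2L]))
  cat(sprintf("  limits of agreement [%.5f, %.5f] Hz\n",
              x$ba_loa_lo, x$ba_loa_hi))
  cat(sprintf("  outside limits     %.2f%%\n", x$pct_outside_loa))
  cat(sprintf("  max rel discrepancy %.3f%%\n", x$max_rel_discrepancy))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x An `agreement_report`.
#' @param a,b The two series the report was computed from (re-aligned for
#'   plotting).
#' @param ... Passed to [graphics::plot()].
#' @export
ba_plot <- function(x, a, b, ...) {
  stopifnot(inherits(x, "agreement_report"))
  al <- align_series(a, b)
  d <- al$a - al$b
  m <- (al$a + al$b) / 2
  graphics::plot(m, d, pch = 20, cex = 0.4,
                 xlab = "mean of methods (Hz)",
                 ylab = "difference (Hz)", ...)
  graphics::abline(h = x$ba_mean_diff, col = 2)
  graphics::abline(h = c(x$ba_loa_lo, x$ba_loa_hi), col = 4, lty = 3)
  invisible(x)
}

#' Maximum relative discrepancy between two heart-rate series
#'
#' `100 * max |a_i - b_i| / b_i` on the common grid, with `b` as the
#' reference series. Edge-affected samples (cone of influence) of either
#' series are excluded.
#'
#' @param a,b Two [hr_series()] with overlapping spans; `b` values must be
#'   positive.
#' @return Maximum relative discrepancy in percent.
#' @export
max_rel_discrepancy <- function(a, b) {
  al <- align_series(a, b)
  keep <- !al$edge
  if (!any(keep)) stop("no non-edge samples in the overlap")
  if (any(al$b[keep] <= 0)) stop("reference series must be positive")
  100 * max(abs(al$a[keep] - al$b[keep]) / al$b[keep])
}

#' LF/HF spectral indices of a heart-rate series
#'
#' Amplitude spectrum of the mean-removed, Hann-tapered series; the band
#' amplitude is the sum of spectral amplitudes within each standard HRV
#' band (VLF 0.0033-0.04, LF 0.04-0.15, HF 0.15-0.4 Hz), normalised by the
#' VLF+LF+HF total. The LF/HF ratio uses the (unnormalised) amplitudes.
#'
#' @param hr An equidistant [hr_series()]; at least 125 s is needed to
#'   resolve the LF band (a warning is issued below that).
#' @return Object of class `spectral_indices`: list with `vlf_n`, `lf_n`,
#'   `hf_n` (sum to 1), `lf_hf`, and the band edges.
#' @export
spectral_indices <- function(hr) {
  stopifnot(inherits(hr, "hr_series"))
  v <- hr$values
  n <- length(v)
  if (n < 8L || stats::sd(v) == 0)
    stop("series empty or constant: spectral indices undefined")
  dur <- (n - 1) / hr$fs_out
  if (dur < 125)
    warning("series shorter than 125 s; LF band poorly resolved")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  A <- Mod(stats::fft((v - mean(v)) * w))
  fr <- (seq_len(n) - 1L) * hr$fs_out / n
  half <- seq(2L, floor(n / 2) + 1L)
  A <- A[half]; fr <- fr[half]
  bands <- list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
  amp <- vapply(bands, function(bd) sum(A[fr >= bd[1L] & fr < bd[2L]]),
                numeric(1))
  # HF band is closed at 0.4 Hz
  amp["hf"] <- amp["hf"] + sum(A[abs(fr - 0.4) < 1e-12])
  tot <- sum(amp)
  if (tot == 0) stop("no spectral amplitude in the VLF/LF/HF bands")
  if (amp["hf"] == 0) stop("zero HF amplitude: LF/HF ratio undefined")
  structure(list(vlf_n = unname(amp["vlf"] / tot),
                 lf_n = unname(amp["lf"] / tot),
                 hf_n = unname(amp["hf"] / tot),
                 lf_hf = unname(amp["lf"] / amp["hf"]),
                 bands = bands),
            class = "spectral_indices")
}

#' @export
print.spectral_indices <- function(x, ...) {
  cat(sprintf(
    "<spectral_indices> VLF %.4f  LF %.4f  HF %.4f (normalised); LF/HF = %.4f\n",
    x$vlf_n, x$lf_n, x$hf_n, x$lf_hf))
  invisible(x)
}
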