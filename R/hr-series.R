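#' Construct an equidistant heart-rate series
#'
#' The common output container of the pipeline: instantaneous heart rate in
#' Hz (beats per second, nu = 1/T) on an equidistant time grid. Gap samples
#' (analysis times where no in-band oscillatory pattern existed before
#' reconciliation) may hold `NA` and are flagged in `gap`; edge-affected
#' samples (cone of influence of the wavelet at the record boundaries) are
#' flagged in `edge` and are excluded from discrepancy statistics.
#'
#' @param times Equidistant times in seconds.
#' @param values Heart rate in Hz; positive and finite except at gap samples.
#' @param provenance One of `"pattern-fundamental"`, `"pattern-harmonic"`,
#'   `"rpeak"`, `"expert"`, `"truth"`.
#' @param fs_out Output sampling rate in Hz. Defaults to `1/median(diff(times))`.
#' @param gap Logical vector flagging unfilled samples (default none).
#' @param edge Logical vector flagging edge-affected samples (default none).
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(times, values,
                      provenance = c("pattern-fundamental", "pattern-harmonic",
                                     "rpeak", "expert", "truth"),
                      fs_out = NULL, gap = NULL, edge = NULL) {
  provenance <- match.arg(provenance)
  times <- as.numeric(times); values <- as.numeric(values)
  n <- length(times)
  if (n < 1L) stop("hr_series must be non-empty")
  if (length(values) != n) stop("times and values must have equal length")
  if (n > 1L) {
    dt <- diff(times)
    if (any(abs(dt - dt[1L]) > 1e-9 * max(abs(dt[1L]), 1)))
      stop("hr_series times must be equidistant")
  }
  if (is.null(gap)) gap <- rep(FALSE, n)
  if (is.null(edge)) edge <- rep(FALSE, n)
  ok <- !gap
  if (any(!is.finite(values[ok])) || any(values[ok] <= 0))
    stop("non-gap heart-rate values must be positive and finite")
  if (is.null(fs_out))
    fs_out <- if (n > 1L) 1 / stats::median(diff(times)) else NA_real_
  structure(list(times = times, values = values, provenance = provenance,
                 fs_out = fs_out, gap = as.logical(gap),
                 edge = as.logical(edge)),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  v <- x$values[!x$gap]
  cat(sprintf(
    "<hr_series> %s: %d samples @ %.4g Hz, span %.1f-%.1f s\n",
    x$provenance, length(x$times), x$fs_out, min(x$times), max(x$times)))
  if (length(v))
    cat(sprintf("  HR mean %.4f Hz (%.1f bpm), range [%.4f, %.4f] Hz; %d gap, %d edge\n",
                mean(v), 60 * mean(v), min(v), max(v),
                sum(x$gap), sum(x$edge)))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$times)

#' @export
as.data.frame.hr_series <- function(x, ...) {
  data.frame(time_s = x$times, hr_hz = x$values,
             provenance = x$provenance, gap = x$gap, edge = x$edge)
}

#' @export
plot.hr_series <- function(x, ..., ylab = "HR (Hz)", xlab = "time (s)",
                           type = "l") {
  graphics::plot(x$times, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  if (any(x$gap))
    graphics::points(x$times[x$gap], x$values[x$gap], col = 2, pch = 20)
  invisible(x)
}

# restrict a series to an index subset (keeps equidistance only if contiguous)
hr_window <- function(x, t_lo, t_hi) {
  keep <- x$times >= t_lo & x$times <= t_hi
  hr_series(x$times[keep], x$values[keep], x$provenance,
            fs_out = x$fs_out, gap = x$gap[keep], edge = x$edge[keep])
}
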