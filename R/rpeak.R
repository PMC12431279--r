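#' Detect R-peaks (classical contour baseline)
#'
#' A classical derivative/energy QRS detector in the Pan--Tompkins lineage:
#' zero-phase band-pass (5--15 Hz), differentiation, squaring, 150 ms
#' moving-window integration, then adaptive dual-threshold peak picking
#' with a 0.25 s refractory period. The reported R location is the maximum
#' of the band-passed signal magnitude within 100 ms of each detection.
#' For PPG records the same adaptive logic is applied to the 0.5--8 Hz
#' band-passed pulse wave directly (systolic peaks).
#'
#' @param record A [signal_record()] of kind ECG (or PPG/PPGd/synthetic for
#'   the pulse-peak variant). At least 5 s of signal is required.
#' @param refractory Minimum inter-beat spacing in seconds (default 0.25).
#' @return A [beat_annotations()] with `source = "detector"`.
#' @export
detect_rpeaks <- function(record, refractory = 0.25) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  x <- record$samples
  if (length(x) < 5 * fs) stop("record shorter than 5 s")
  if (stats::sd(x) == 0) stop("zero-variance signal: no beats to detect")
  refr <- as.integer(round(refractory * fs))

  if (record$kind %in% c("PPG", "PPGd")) {
    bp <- bp_filter(x, fs, 0.5, min(8, 0.45 * fs), order = 2L)
    feat <- bp
    search <- bp
  } else {
    bp <- bp_filter(x, fs, 5, min(15, 0.45 * fs), order = 3L)
    d <- c(diff(bp), 0)
    feat <- moving_avg(d^2, max(3L, as.integer(round(0.15 * fs))))
    search <- abs(bp)
  }

  # candidate peaks of the feature signal
  n <- length(feat)
  cand <- which(diff(sign(diff(feat))) < 0) + 1L
  cand <- cand[feat[cand] > 0]
  if (!length(cand)) stop("no candidate peaks found")

  # adaptive dual thresholds (signal / noise running estimates)
  init <- feat[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(init); npk <- mean(init)
  thr <- npk + 0.25 * (spk - npk)
  beats <- integer(0)
  last <- -Inf
  for (p in cand) {
    v <- feat[p]
    if (p - last < refr) next
    if (v > thr) {
      beats <- c(beats, p)
      last <- p
      spk <- 0.125 * v + 0.875 * spk
    } else {
      npk <- 0.125 * v + 0.875 * npk
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  if (!length(beats)) stop("no beats detected above threshold")

  # refine to the R-wave location on the band-passed signal
  w <- as.integer(round(0.10 * fs))
  ref <- vapply(beats, function(p) {
    lo <- max(1L, p - w); hi <- min(n, p + w)
    lo + which.max(search[lo:hi]) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # merge refinements that collapsed within the refractory period
  if (length(ref) > 1L) {
    keep <- c(TRUE, diff(ref) >= refr)
    ref <- ref[keep]
  }
  beat_annotations(ref, source = "detector")
}

#' Beat annotations to non-equidistant heart rate
#'
#' Converts inter-beat intervals to instantaneous rate, nu = 1/T: one value
#' per interval, stamped at the interval midpoint.
#'
#' @param ann A [beat_annotations()].
#' @param fs Sampling rate in Hz of the record the indices refer to.
#' @return Object of class `ne_hr`: list with `times` (s, strictly
#'   increasing interval midpoints), `values` (Hz), `source`.
#' @export
annotations_to_hr <- function(ann, fs) {
  stopifnot(inherits(ann, "beat_annotations"))
  idx <- ann$peak_indices
  if (length(idx) < 2L) stop("need at least 2 beats")
  if (any(diff(idx) == 0L)) stop("duplicate beat indices")
  iv <- diff(idx) / fs
  structure(list(times = (idx[-length(idx)] + idx[-1L]) / 2 / fs,
                 values = 1 / iv, source = ann$source),
            class = "ne_hr")
}

#' @export
print.ne_hr <- function(x, ...) {
  cat(sprintf("<ne_hr> %d intervals (%s); HR mean %.4f Hz\n",
              length(x$values), x$source, mean(x$values)))
  invisible(x)
}

#' Interpolate non-equidistant heart rate to an equidistant grid
#'
#' Linear interpolation of the beat-interval rate values onto a uniform
#' grid, for comparison with the continuous pattern-method output.
#'
#' @param hr An `ne_hr` from [annotations_to_hr()].
#' @param fs_out Output rate in Hz.
#' @param t_start,t_end Grid span in seconds; must lie within the data span
#'   (no extrapolation). Defaults to the data span.
#' @param method `"linear"` or `"constant"` (stepwise).
#' @return An [hr_series()] with provenance `"rpeak"` or `"expert"`.
#' @export
to_equidistant <- function(hr, fs_out, t_start = NULL, t_end = NULL,
                           method = c("linear", "constant")) {
  stopifnot(inherits(hr, "ne_hr"))
  method <- match.arg(method)
  if (length(hr$times) < 2L) stop("need at least 2 rate points")
  if (is.null(t_start)) t_start <- hr$times[1L]
  if (is.null(t_end)) t_end <- hr$times[length(hr$times)]
  if (t_start < hr$times[1L] - 1e-9 || t_end > hr$times[length(hr$times)] + 1e-9)
    stop("extrapolation outside the data span requested")
  grid <- seq(t_start, t_end, by = 1 / fs_out)
  v <- stats::approx(hr$times, hr$values, xout = grid, method = method,
                     rule = 2)$y
  hr_series(grid, v,
            if (hr$source == "expert") "expert" else "rpeak",
            fs_out = fs_out)
}
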