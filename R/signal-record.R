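#' Construct a signal record
#'
#' A `signal_record` holds a single channel of a physiological time series:
#' the raw samples (arbitrary amplitude units, e.g. mV), the sampling rate
#' and the signal kind. All downstream analysis (wavelet transform, R-peak
#' detection) starts from this container.
#'
#' @param samples Numeric vector of amplitudes. Must be finite and non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param kind One of `"ECG"`, `"PPG"`, `"PPGd"`, `"synthetic"`.
#' @param label Free-text channel name.
#' @param t0 Start-time offset in seconds (default 0).
#'
#' @return An object of class `signal_record`: a list with elements
#'   `samples`, `fs`, `kind`, `label`, `t0`.
#' @examples
#' rec <- signal_record(sin(2 * pi * seq(0, 10, by = 1 / 250)), fs = 250)
#' rec
#' @export
signal_record <- function(samples, fs, kind = "synthetic", label = "", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("signal record must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("signal record contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  kind <- match.arg(kind, c("ECG", "PPG", "PPGd", "synthetic"))
  structure(
    list(samples = samples, fs = fs, kind = kind,
         label = as.character(label)[1L], t0 = as.numeric(t0)[1L]),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s%s: %d samples @ %g Hz (%.1f s)\n",
              x$kind, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Sample times of a signal record
#'
#' @param record A [signal_record()].
#' @return Numeric vector of sample times in seconds (`t0 + (i-1)/fs`).
#' @export
record_times <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  record$t0 + (seq_along(record$samples) - 1) / record$fs
}

#' Construct beat annotations
#'
#' Beat annotations are strictly increasing sample indices marking detected
#' or expert-annotated heart beats (R-peak locations for ECG, systolic peaks
#' for PPG).
#'
#' @param peak_indices Integer vector of 1-based sample indices, strictly
#'   increasing.
#' @param source `"detector"` or `"expert"`.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(peak_indices, source = "detector") {
  peak_indices <- as.integer(round(peak_indices))
  if (length(peak_indices) && any(diff(peak_indices) <= 0))
    stop("beat annotation indices must be strictly increasing")
  if (length(peak_indices) && any(peak_indices < 1L))
    stop("beat annotation indices must be positive")
  source <- match.arg(source, c("detector", "expert"))
  structure(list(peak_indices = peak_indices, source = source),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats (%s)\n",
              length(x$peak_indices), x$source))
  invisible(x)
}
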