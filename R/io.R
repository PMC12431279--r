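#' Read a physiological signal record
#'
#' Reads one channel of an ECG/PPG recording into a [signal_record()].
#' Supported formats:
#' \describe{
#'   \item{`csv`}{Comma-separated with a mandatory header row and dot
#'     decimals; the channel is a column name or index. CSV carries no
#'     sampling rate, so `fs` must be supplied.}
#'   \item{`wfdb`}{WFDB header/signal pairs (`.hea` + `.dat`), formats 16
#'     and 212; `path` is the header file or the record name without
#'     extension. `fs` is taken from the header.}
#'   \item{`edf`}{European Data Format (EDF, 16-bit); `fs` is taken from
#'     the header. EDF+ annotations are not supported.}
#' }
#' Samples are never resampled or filtered at load time; the output length
#' equals the stored length.
#'
#' @param path File path (for WFDB, the `.hea` file or the record stem).
#' @param format `"csv"`, `"wfdb"` or `"edf"`.
#' @param channel Channel name or 1-based index (default 1).
#' @param fs Sampling rate in Hz; required for `csv`, ignored otherwise.
#' @param kind Signal kind stored on the record (default `"ECG"`).
#' @return A [signal_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb", "edf"),
                        channel = 1L, fs = NULL, kind = "ECG") {
  format <- match.arg(format)
  switch(format,
         csv = .read_record_csv(path, channel, fs, kind),
         wfdb = .read_record_wfdb(path, channel, kind),
         edf = .read_record_edf(path, channel, kind))
}

.read_record_csv <- function(path, channel, fs, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(fs)) stop("'fs' must be supplied for CSV input")
  df <- utils::read.csv(path, header = TRUE)
  if (is.character(channel)) {
    if (!channel %in% names(df)) stop("unknown channel: ", channel)
    col <- df[[channel]]
    label <- channel
  } else {
    channel <- as.integer(channel)
    if (channel < 1L || channel > ncol(df)) stop("unknown channel index ", channel)
    col <- df[[channel]]
    label <- names(df)[channel]
  }
  v <- suppressWarnings(as.numeric(col))
  if (anyNA(v)) stop("non-numeric samples in channel ", label)
  signal_record(v, fs, kind = kind, label = label)
}

#' Write a signal record as CSV
#'
#' One header row (`value`) and one sample per line, at full double
#' precision (15 significant digits).
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("value", con)
  writeLines(formatC(record$samples, digits = 15, format = "g"), con)
  invisible(path)
}

#' Read beat annotations
#'
#' `csv`: a header-optional list of strictly increasing 1-based sample
#' indices (comma- or newline-separated). `wfdb`: a binary MIT-format
#' annotation file (e.g. `.atr`); only beat-class annotations (normal and
#' ectopic) are retained, rhythm/noise/comment marks are dropped.
#'
#' @param path Annotation file path.
#' @param format `"csv"` or `"wfdb"`.
#' @param source Annotation provenance, `"expert"` (default) or
#'   `"detector"`.
#' @return A [beat_annotations()].
#' @export
read_annotations <- function(path, format = c("csv", "wfdb"),
                             source = "expert") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  idx <- switch(format,
                csv = .read_ann_csv(path),
                wfdb = read_wfdb_annotations(path))
  if (!length(idx)) stop("no beat annotations found in ", path)
  if (any(diff(idx) <= 0)) stop("annotation indices are not strictly increasing")
  beat_annotations(idx, source = source)
}

.read_ann_csv <- function(path) {
  tok <- scan(path, what = character(), sep = ",", quiet = TRUE,
              strip.white = TRUE)
  tok <- tok[nzchar(tok)]
  v <- suppressWarnings(as.numeric(tok))
  if (length(v) && is.na(v[1L]) && length(v) > 1L) {  # header token
    tok <- tok[-1L]; v <- v[-1L]
  }
  if (anyNA(v)) stop("non-numeric annotation indices in ", path)
  as.integer(round(v))
}

#' Write a heart-rate series as CSV
#'
#' Header `time_s,hr_hz,provenance`; values at 12 significant digits so a
#' read-back reproduces them to at least 9 significant digits.
#'
#' @param hr A non-empty [hr_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_hr <- function(hr, path) {
  stopifnot(inherits(hr, "hr_series"))
  if (length(hr$times) < 1L) stop("empty series")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,hr_hz,provenance", con)
  writeLines(sprintf("%s,%s,%s",
                     formatC(hr$times, digits = 12, format = "g"),
                     formatC(hr$values, digits = 12, format = "g"),
                     hr$provenance), con)
  invisible(path)
}

#' Read a heart-rate series written by [write_hr()]
#'
#' @param path CSV file path with columns `time_s`, `hr_hz`, `provenance`.
#' @return An [hr_series()].
#' @export
read_hr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("time_s", "hr_hz", "provenance") %in% names(df)))
    stop("not a heart-rate CSV (need time_s,hr_hz,provenance)")
  hr_series(df$time_s, df$hr_hz, as.character(df$provenance[1L]))
}
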