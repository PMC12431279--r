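# internal helpers

# Run code with a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Strict interior local maxima of a numeric vector on a discrete grid.
# Plateaus of exact ties count once, at their leftmost cell, and only when
# the value drops on both sides; endpoints are never maxima.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  res <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) res <- c(res, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

# Zero-phase Butterworth filtering with edge-safe fallback for very short
# signals (filtfilt needs a few filter lengths of data).
bp_filter <- function(x, fs, lo, hi, order = 3L) {
  ny <- fs / 2
  w <- c(lo, hi) / ny
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  bf <- signal::butter(order, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lp_filter <- function(x, fs, hi, order = 2L) {
  ny <- fs / 2
  bf <- signal::butter(order, min(hi / ny, 1 - 1e-6), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# centred moving average over an odd window of w samples
moving_avg <- function(x, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # fill the NA edges with the nearest computed value
  idx <- which(!is.na(y))
  if (length(idx)) {
    y[seq_len(idx[1L] - 1L)] <- y[idx[1L]]
    y[seq.int(idx[length(idx)] + 1L, length.out = length(y) - idx[length(idx)])] <-
      y[idx[length(idx)]]
  }
  y
}
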