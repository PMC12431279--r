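#' Morlet wavelet
#'
#' The complex Morlet mother wavelet used throughout the package,
#' \deqn{\psi(\eta) = \pi^{-1/4} \exp(2\pi j \eta) \exp(-\eta^2/2),}
#' i.e. a unit-frequency complex carrier under a Gaussian envelope: one
#' oscillation per unit of the dimensionless argument \eqn{\eta}. With the
#' transform's argument convention \eqn{\eta = f (t - t_0)} the scale
#' parameter \eqn{f} is read directly as pseudo-frequency in Hz; no
#' centre-frequency correction is applied.
#'
#' @param eta Dimensionless argument (numeric vector).
#' @return Complex vector of the same length.
#' @examples
#' morlet(0)            # pi^(-1/4)
#' Mod(morlet(1))       # pi^(-1/4) * exp(-1/2)
#' @export
morlet <- function(eta) {
  if (!all(is.finite(eta))) stop("'eta' must be finite")
  pi^(-1 / 4) * exp(2i * pi * eta) * exp(-eta^2 / 2)
}

#' Construct a frequency grid
#'
#' Linearly spaced analysis frequencies for the wavelet transform. The
#' default cardiac analysis range is 0.5--1.5 Hz with a 0.005 Hz step, which
#' gives roughly 100--160 bins across a fundamental or harmonic band.
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param step Grid step in Hz.
#' @return Object of class `frequency_grid`: list with `freqs`, `f_lo`,
#'   `f_hi`, `n_freqs`.
#' @export
frequency_grid <- function(f_lo = 0.5, f_hi = 1.5, step = 0.005) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  freqs <- seq(f_lo, f_hi, by = step)
  if (freqs[length(freqs)] < f_hi - 1e-12) freqs <- c(freqs, f_hi)
  structure(list(freqs = freqs, f_lo = f_lo, f_hi = f_hi,
                 n_freqs = length(freqs)),
            class = "frequency_grid")
}

# half-width of the truncated wavelet support, in samples, at frequency f:
# the Gaussian envelope is cut at |eta| <= 5 (envelope < 4e-6)
.cwt_halfwidth <- function(f, fs) as.integer(ceiling(5 * fs / f))

#' Continuous wavelet transform of a signal record
#'
#' Computes the discretised Morlet CWT
#' \deqn{W(f, t_0) = f\, \Delta t \sum_t x(t)\, \psi^*(f (t - t_0))}
#' on a linear frequency grid, evaluated at analysis times decimated by an
#' integer stride (default 10, so the output rate is `fs/10`). The linear
#' prefactor `f` compensates the `1/f` time-width of the wavelet at scale
#' `1/f`, so the energy ridge of a pure tone peaks exactly at the tone
#' frequency (a `sqrt(f)` normalisation would bias the scalogram argmax low
#' by about `f/(8*pi^2)`). The infinite sum is truncated at
#' \eqn{|\eta| \le 5}, where the Gaussian envelope is below 4e-6. Cells
#' whose truncated support window extends past the record edges (the cone
#' of influence) are flagged in the `edge` matrix and should be excluded
#' from ridge statistics.
#'
#' The transform is evaluated by FFT convolution, one frequency row at a
#' time; [cwt_direct()] is the plain direct-sum evaluation of the same
#' quantity, retained as a slow reference.
#'
#' @param record A [signal_record()].
#' @param grid A [frequency_grid()]; must lie inside `(0, fs/2)`.
#' @param decimation Positive integer time stride in samples (default 10).
#' @return Object of class `tf_surface`: list with `times` (s), `freqs`
#'   (Hz), complex matrix `W` (time x frequency), energy matrix `E = |W|^2`,
#'   logical matrix `edge`, and `decimation`, `fs`.
#' @seealso [energy_surface()], [extract_skeleton()]
#' @export
compute_cwt <- function(record, grid, decimation = 10L) {
  stopifnot(inherits(record, "signal_record"), inherits(grid, "frequency_grid"))
  decimation <- as.integer(decimation)
  if (decimation < 1L) stop("'decimation' must be a positive integer")
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  freqs <- grid$freqs
  if (grid$f_hi >= fs / 2) stop("frequency grid exceeds the Nyquist limit")
  m_max <- .cwt_halfwidth(freqs[1L], fs)
  if (n < m_max + 1L)
    stop(sprintf(
      "record too short (%d samples) for the wavelet support at %g Hz (%d samples)",
      n, freqs[1L], m_max + 1L))

  idx <- seq.int(1L, n, by = decimation)          # analysis sample indices
  times <- record$t0 + (idx - 1L) / fs
  nf <- length(freqs)
  nt <- length(idx)
  W <- matrix(complex(real = 0, imaginary = 0), nt, nf)
  edge <- matrix(FALSE, nt, nf)

  N <- stats::nextn(n + 2L * m_max + 1L, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  dt <- 1 / fs
  for (k in seq_len(nf)) {
    f <- freqs[k]
    M <- .cwt_halfwidth(f, fs)
    tau <- (-M:M) * dt
    kern <- Conj(morlet(f * tau))               # psi*(f (t - t0))
    h <- rev(kern)                              # correlation via convolution
    H <- stats::fft(c(h, rep(0, N - length(h))))
    y <- stats::fft(X * H, inverse = TRUE) / N
    # full convolution index s = i + M gives the correlation at sample i
    W[, k] <- f * dt * y[idx + M]
    edge[, k] <- (idx <= M) | (idx > n - M)
  }
  structure(list(times = times, freqs = freqs, W = W, E = Mod(W)^2,
                 edge = edge, decimation = decimation, fs = fs),
            class = "tf_surface")
}

#' Direct-sum reference evaluation of the Morlet CWT
#'
#' Evaluates the truncated transform sum literally, term by term, with no
#' FFT acceleration. Quadratic cost; intended for validation on short
#' records and for inspecting individual cells.
#'
#' @inheritParams compute_cwt
#' @return Same structure as [compute_cwt()].
#' @export
cwt_direct <- function(record, grid, decimation = 10L) {
  stopifnot(inherits(record, "signal_record"), inherits(grid, "frequency_grid"))
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  freqs <- grid$freqs
  idx <- seq.int(1L, n, by = as.integer(decimation))
  times <- record$t0 + (idx - 1L) / fs
  nt <- length(idx); nf <- length(freqs)
  W <- matrix(complex(real = 0, imaginary = 0), nt, nf)
  edge <- matrix(FALSE, nt, nf)
  dt <- 1 / fs
  for (k in seq_len(nf)) {
    f <- freqs[k]
    M <- .cwt_halfwidth(f, fs)
    for (i in seq_len(nt)) {
      i0 <- idx[i]
      lo <- max(1L, i0 - M); hi <- min(n, i0 + M)
      tau <- (seq.int(lo, hi) - i0) * dt
      W[i, k] <- f * dt * sum(x[lo:hi] * Conj(morlet(f * tau)))
      edge[i, k] <- (i0 <= M) | (i0 > n - M)
    }
  }
  structure(list(times = times, freqs = freqs, W = W, E = Mod(W)^2,
                 edge = edge, decimation = as.integer(decimation), fs = fs),
            class = "tf_surface")
}

#' Energy surface of a wavelet transform
#'
#' Fills (or refreshes) the energy matrix `E = |W|^2` of a time-frequency
#' surface. Idempotent.
#'
#' @param surface A `tf_surface` from [compute_cwt()].
#' @return The surface with `E` set to the squared modulus of `W`.
#' @export
energy_surface <- function(surface) {
  stopifnot(inherits(surface, "tf_surface"))
  if (is.null(surface$W)) stop("surface has no coefficient matrix W")
  surface$E <- Mod(surface$W)^2
  surface
}

#' @export
print.tf_surface <- function(x, ...) {
  cat(sprintf(
    "<tf_surface> %d times x %d freqs; f in [%g, %g] Hz; dt = %g s\n",
    nrow(x$W), ncol(x$W), min(x$freqs), max(x$freqs),
    x$decimation / x$fs))
  invisible(x)
}

#' Export an energy surface as a long data frame
#'
#' @param x A `tf_surface`.
#' @param ... Unused.
#' @return Data frame with columns `time_s`, `freq_hz`, `energy`, `edge`.
#' @export
as.data.frame.tf_surface <- function(x, ...) {
  data.frame(time_s = rep(x$times, times = length(x$freqs)),
             freq_hz = rep(x$freqs, each = length(x$times)),
             energy = as.vector(x$E),
             edge = as.vector(x$edge))
}
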