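#' Synthetic-signal configuration
#'
#' Parameters of the seeded synthetic ECG/PPG generator. The defaults
#' emulate a resting adult recording: 250 Hz sampling, mean rate 1 Hz
#' (60 bpm) with small LF (0.1 Hz) and HF (0.3 Hz) rate modulation, plus a
#' slow random rate-jitter component low-passed at 0.4 Hz so the true rate
#' stays inside the standard HRV bands.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz (default 250).
#' @param mean_rate Mean heart rate in Hz (default 1.0).
#' @param lf_amp,lf_freq LF rate-modulation amplitude (Hz) and frequency
#'   (Hz); defaults 0.03 and 0.1.
#' @param hf_amp,hf_freq HF rate-modulation amplitude and frequency;
#'   defaults 0.03 and 0.3.
#' @param rate_jitter_sd SD of the smoothed random rate jitter in Hz
#'   (default 0.01).
#' @param morphology `"ecg"` or `"ppg"` beat template.
#' @param noise_snr_db Additive white-noise level as signal-to-noise ratio
#'   in dB (`Inf` = clean, the default).
#' @param wander_amp Baseline-wander amplitude as a fraction of the signal
#'   SD (default 0 = none).
#' @param artifacts List of motion-artifact windows, each
#'   `c(t_start, t_end, amplitude_scale)` (scale in units of signal SD).
#' @param decimation Stride defining the ground-truth rate grid
#'   (`fs/decimation`, matching the pipeline output grid; default 10).
#' @param seed Integer RNG seed; every stochastic component derives from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(duration = 300, fs = 250, mean_rate = 1.0,
                         lf_amp = 0.03, lf_freq = 0.1,
                         hf_amp = 0.03, hf_freq = 0.3,
                         rate_jitter_sd = 0.01,
                         morphology = c("ecg", "ppg"),
                         noise_snr_db = Inf, wander_amp = 0,
                         artifacts = list(),
                         decimation = 10L, seed = 1L) {
  morphology <- match.arg(morphology)
  if (mean_rate - lf_amp - hf_amp <= 0.3)
    stop("rate modulation too deep: mean_rate - lf_amp - hf_amp must exceed 0.3 Hz")
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  structure(list(duration = duration, fs = fs, mean_rate = mean_rate,
                 lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq,
                 rate_jitter_sd = rate_jitter_sd, morphology = morphology,
                 noise_snr_db = noise_snr_db, wander_amp = wander_amp,
                 artifacts = artifacts, decimation = as.integer(decimation),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# instantaneous rate at full sampling resolution (internal)
.hr_truth_full <- function(config) {
  n <- as.integer(round(config$duration * config$fs))
  t <- (seq_len(n) - 1L) / config$fs
  hr <- config$mean_rate +
    config$lf_amp * sin(2 * pi * config$lf_freq * t) +
    config$hf_amp * sin(2 * pi * config$hf_freq * t)
  if (config$rate_jitter_sd > 0) {
    jit <- with_seed(config$seed, stats::rnorm(n))
    jit <- lp_filter(jit, config$fs, 0.4, order = 2L)
    jit <- jit / stats::sd(jit) * config$rate_jitter_sd
    hr <- hr + jit
  }
  list(t = t, hr = hr)
}

#' Ground-truth instantaneous heart rate
#'
#' The prescribed rate trajectory
#' `HR(t) = mean_rate + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi hf_freq t) + jitter(t)`,
#' sampled on the pipeline's output grid (`fs/decimation`). The jitter is
#' seeded white noise low-passed at 0.4 Hz and rescaled to
#' `rate_jitter_sd`.
#'
#' @param config A [synth_config()].
#' @return An [hr_series()] with provenance `"truth"`.
#' @export
generate_hr_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  full <- .hr_truth_full(config)
  idx <- seq.int(1L, length(full$t), by = config$decimation)
  hr_series(full$t[idx], full$hr[idx], "truth",
            fs_out = config$fs / config$decimation)
}

#' Place beats by integrating the rate (integrate-and-fire)
#'
#' Beat times are the crossings of the cumulative phase
#' `Phi(t) = integral_0^t HR(tau) dtau` through successive integers, so the
#' integral of the rate between consecutive beats is exactly one cycle and
#' the instantaneous-rate ground truth is exact by construction.
#'
#' @param truth An [hr_series()] of provenance `"truth"`, or a
#'   [synth_config()] (in which case the full-resolution rate is used).
#' @param config A [synth_config()] supplying `fs` when `truth` is a
#'   series; ignored otherwise.
#' @return Numeric vector of beat times in seconds.
#' @export
synthesize_beats <- function(truth, config = NULL) {
  if (inherits(truth, "synth_config")) {
    full <- .hr_truth_full(truth)
    t <- full$t; hr <- full$hr
  } else {
    stopifnot(inherits(truth, "hr_series"))
    t <- truth$times; hr <- truth$values
  }
  if (any(hr <= 0)) stop("rate must be positive everywhere")
  dt <- t[2L] - t[1L]
  # trapezoidal cumulative phase
  phi <- c(0, cumsum((hr[-1L] + hr[-length(hr)]) / 2 * dt))
  k <- seq_len(floor(phi[length(phi)]))
  if (!length(k)) return(numeric(0))
  # invert the monotone phase by linear interpolation
  stats::approx(phi, t, xout = k)$y
}

# Gaussian bump helper
.gauss <- function(t, mu, sd) exp(-((t - mu)^2) / (2 * sd^2))

#' Synthesise an ECG-like signal from beat times
#'
#' Each beat contributes a sharp biphasic QRS template — a narrow Gaussian
#' R-wave (sd 8 ms, amplitude 1, maximum exactly at the beat time) with a
#' small negative S-dip 40 ms later — plus low-amplitude P (before) and T
#' (after) Gaussian bumps.
#'
#' @param beat_times Beat times in seconds, within `[0, duration]`.
#' @param config A [synth_config()].
#' @return A [signal_record()] of kind `"ECG"`.
#' @export
synthesize_ecg <- function(beat_times, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$duration * config$fs))
  t <- (seq_len(n) - 1L) / config$fs
  x <- numeric(n)
  half <- 0.35   # template support half-width, s
  for (tb in beat_times) {
    lo <- max(1L, as.integer(floor((tb - half) * config$fs)) + 1L)
    hi <- min(n, as.integer(ceiling((tb + half) * config$fs)) + 1L)
    tt <- t[lo:hi]
    x[lo:hi] <- x[lo:hi] +
      1.00 * .gauss(tt, tb, 0.008) -      # R
      0.25 * .gauss(tt, tb + 0.040, 0.012) -  # S dip
      0.10 * .gauss(tt, tb - 0.060, 0.012) +  # Q dip
      0.12 * .gauss(tt, tb - 0.180, 0.025) +  # P
      0.25 * .gauss(tt, tb + 0.250, 0.060)    # T
  }
  signal_record(x, config$fs, kind = "ECG", label = "synthetic ECG")
}

#' Synthesise a PPG-like signal from beat times
#'
#' Each beat contributes a smooth asymmetric pulse (fast ~0.15 s rise,
#' slow ~0.45 s decay, from a difference of exponentials) with a small
#' dicrotic bump on the decay. `synthesize_ppgd()` returns the
#' first-difference variant (scaled by `fs`), emulating a differential
#' photoplethysmograph channel.
#'
#' @param beat_times Beat times in seconds.
#' @param config A [synth_config()].
#' @return A [signal_record()] of kind `"PPG"` (or `"PPGd"`).
#' @export
synthesize_ppg <- function(beat_times, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$duration * config$fs))
  t <- (seq_len(n) - 1L) / config$fs
  x <- numeric(n)
  tau_d <- 0.45; tau_r <- 0.08
  # peak of exp(-tau/tau_d) - exp(-tau/tau_r) and its value, for scaling
  tpk <- log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  pk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  for (tb in beat_times) {
    lo <- max(1L, as.integer(floor(tb * config$fs)) + 1L)
    hi <- min(n, as.integer(ceiling((tb + 1.2) * config$fs)) + 1L)
    if (lo > n) next
    tau <- t[lo:hi] - tb
    pulse <- (exp(-tau / tau_d) - exp(-tau / tau_r)) / pk
    pulse[tau < 0] <- 0
    pulse <- pulse + 0.15 * .gauss(tau, 0.42, 0.05)
    x[lo:hi] <- x[lo:hi] + pulse
  }
  signal_record(x, config$fs, kind = "PPG", label = "synthetic PPG")
}

#' @rdname synthesize_ppg
#' @export
synthesize_ppgd <- function(beat_times, config) {
  ppg <- synthesize_ppg(beat_times, config)
  d <- c(diff(ppg$samples), 0) * config$fs
  signal_record(d, config$fs, kind = "PPGd", label = "synthetic PPGd")
}

#' Corrupt a record with noise, baseline wander and motion artifacts
#'
#' Adds (all seeded from `config$seed`): white Gaussian noise scaled to the
#' requested signal-to-noise ratio; baseline wander (integrated white noise
#' low-passed below 0.5 Hz, scaled to `wander_amp` times the signal SD);
#' and, inside each artifact window, a large band-limited (5--15 Hz) burst
#' of `amplitude_scale` times the signal SD. With `noise_snr_db = Inf`,
#' `wander_amp = 0` and no artifact windows the record is returned
#' unchanged.
#'
#' @param record A [signal_record()].
#' @param config A [synth_config()].
#' @return A corrupted [signal_record()] of the same kind and length.
#' @export
corrupt <- function(record, config) {
  stopifnot(inherits(record, "signal_record"), inherits(config, "synth_config"))
  x <- record$samples
  n <- length(x)
  fs <- record$fs
  sx <- stats::sd(x)
  clean <- is.infinite(config$noise_snr_db) && config$wander_amp == 0 &&
    length(config$artifacts) == 0L
  if (clean) return(record)
  x <- with_seed(config$seed + 1L, {
    if (is.finite(config$noise_snr_db)) {
      target_var <- stats::var(x) / 10^(config$noise_snr_db / 10)
      noise <- stats::rnorm(n)
      noise <- noise / stats::sd(noise) * sqrt(target_var)
      x <- x + noise
    }
    if (config$wander_amp > 0) {
      wander <- lp_filter(cumsum(stats::rnorm(n)), fs, 0.45, order = 2L)
      x <- x + wander / stats::sd(wander) * config$wander_amp * sx
    }
    for (aw in config$artifacts) {
      lo <- max(1L, as.integer(round(aw[1L] * fs)) + 1L)
      hi <- min(n, as.integer(round(aw[2L] * fs)))
      if (hi <= lo) next
      burst <- bp_filter(stats::rnorm(hi - lo + 1L), fs, 5, min(15, 0.45 * fs),
                         order = 2L)
      # Tukey-style taper so the burst enters and leaves smoothly
      m <- hi - lo + 1L
      ramp <- pmin(1, seq_len(m) / (0.1 * m), rev(seq_len(m)) / (0.1 * m))
      x[lo:hi] <- x[lo:hi] + burst / stats::sd(burst) * aw[3L] * sx * ramp
    }
    x
  })
  signal_record(x, fs, kind = record$kind,
                label = paste(record$label, "(corrupted)"), t0 = record$t0)
}

#' One-call synthetic record
#'
#' Convenience wrapper: ground truth, beats, morphology and corruption in
#' one step.
#'
#' @param config A [synth_config()].
#' @return List with `record` ([signal_record()]), `truth` ([hr_series()]),
#'   `beat_times` (s).
#' @export
simulate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- generate_hr_truth(config)
  beats <- synthesize_beats(config)
  rec <- if (config$morphology == "ppg") synthesize_ppg(beats, config)
         else synthesize_ecg(beats, config)
  list(record = corrupt(rec, config), truth = truth, beat_times = beats)
}
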