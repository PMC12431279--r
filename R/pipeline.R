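#' Frequency band specification
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param role `"fundamental"` or `"harmonic"`.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(f_lo, f_hi, role = c("fundamental", "harmonic")) {
  role <- match.arg(role)
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi, role = role), class = "band_spec")
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the oscillatory-pattern heart-rate
#' pipeline. Defaults reproduce the reference analysis settings: a
#' 0.005 Hz frequency grid, tenfold time decimation (25 Hz output at a
#' 250 Hz recording), epsilon = 0.04 Hz with at most 25 skeletons per time,
#' a fundamental search range of 0.5--2 Hz and bands of +/-20% about the
#' fundamental and its double.
#'
#' @param grid_step CWT frequency-grid step in Hz.
#' @param decimation Integer time stride in samples.
#' @param linking A [linking_params()].
#' @param fmain_range Length-2 numeric search range for the fundamental
#'   frequency, in Hz.
#' @param band_width Half-width of the analysis bands as a fraction of the
#'   band centre; must lie in (0, 0.5).
#' @param gap_fill `"harmonic"` (substitute the halved harmonic ridge, then
#'   linearly interpolate what remains) or `"linear"` (interpolate only).
#' @param max_gap_s Longest gap in seconds tolerated without a warning.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_step = 0.005, decimation = 10L,
                            linking = linking_params(),
                            fmain_range = c(0.5, 2.0), band_width = 0.2,
                            gap_fill = c("harmonic", "linear"),
                            max_gap_s = 2) {
  gap_fill <- match.arg(gap_fill)
  if (!(band_width > 0 && band_width < 0.5))
    stop("'band_width' must lie in (0, 0.5)")
  stopifnot(inherits(linking, "linking_params"),
            length(fmain_range) == 2L, fmain_range[1L] > 0,
            fmain_range[2L] > fmain_range[1L], grid_step > 0)
  structure(list(grid_step = grid_step, decimation = as.integer(decimation),
                 linking = linking, fmain_range = as.numeric(fmain_range),
                 band_width = band_width, gap_fill = gap_fill,
                 max_gap_s = max_gap_s),
            class = "pipeline_config")
}

#' Estimate the fundamental cardiac frequency by FFT
#'
#' Takes the amplitude spectrum of the whole (mean-removed, Hann-tapered)
#' record and returns the frequency of the dominant peak within the search
#' range. Cardiac signals, ECG especially, are harmonic-rich, so the raw
#' argmax may land on the second harmonic: if the spectrum has a peak near
#' half the chosen frequency whose amplitude is at least 40% of the chosen
#' peak, that subharmonic is returned instead.
#'
#' @param record A [signal_record()]; at least 60 s is recommended (a
#'   warning is issued below that).
#' @param search_lo,search_hi Search range in Hz, inside `(0, fs/2)`.
#' @return The fundamental frequency estimate in Hz.
#' @export
estimate_fmain <- function(record, search_lo = 0.5, search_hi = 2.0) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (!(search_lo > 0 && search_hi > search_lo && search_hi < fs / 2))
    stop("degenerate search range")
  x <- record$samples
  n <- length(x)
  if (n / fs < 60)
    warning("record shorter than 60 s; fundamental-frequency estimate may be unstable")
  if (stats::sd(x) == 0)
    stop("no dominant peak: signal has zero variance")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann taper
  A <- Mod(stats::fft((x - mean(x)) * w))
  fr <- (seq_len(n) - 1L) * fs / n
  half <- seq_len(floor(n / 2) + 1L)
  A <- A[half]; fr <- fr[half]
  inr <- which(fr >= search_lo & fr <= search_hi)
  if (!length(inr) || max(A[inr]) <= 0)
    stop("no dominant peak in the search range")
  kstar <- inr[which.max(A[inr])]
  fstar <- fr[kstar]; astar <- A[kstar]
  # subharmonic check: a strong peak near fstar/2 means fstar is the
  # second harmonic of the true fundamental
  df <- fs / n
  halfwin <- max(0.05 * fstar, 3 * df)
  sub <- which(fr >= fstar / 2 - halfwin & fr <= fstar / 2 + halfwin &
                 fr >= search_lo)
  if (length(sub)) {
    ksub <- sub[which.max(A[sub])]
    if (A[ksub] >= 0.4 * astar) return(fr[ksub])
  }
  fstar
}

#' Build the fundamental and double-harmonic analysis bands
#'
#' The fundamental band is `[Fmain*(1-w), Fmain*(1+w)]` and the harmonic
#' band is the same relative window about `2*Fmain`; with `Fmain = 1` and
#' the default `w = 0.2` these are \[0.8, 1.2\] Hz and \[1.6, 2.4\] Hz.
#'
#' @param fmain Fundamental frequency in Hz (> 0).
#' @param width_fraction Relative half-width `w`, in (0, 0.5).
#' @return List with elements `fundamental` and `harmonic`, each a
#'   [band_spec()].
#' @export
make_bands <- function(fmain, width_fraction = 0.2) {
  if (!(fmain > 0)) stop("'fmain' must be positive")
  if (!(width_fraction > 0 && width_fraction < 0.5))
    stop("'width_fraction' must lie in (0, 0.5)")
  w <- width_fraction
  list(fundamental = band_spec(fmain * (1 - w), fmain * (1 + w), "fundamental"),
       harmonic = band_spec(2 * fmain * (1 - w), 2 * fmain * (1 + w), "harmonic"))
}

# Fill NA gaps in a ridge: first substitute donor values where available,
# then linearly interpolate what remains (nearest value at the ends).
# Returns list(values, provenance_code): 0 = ridge, 1 = donor, 2 = interp.
.fill_gaps <- function(values, donor = NULL) {
  prov <- integer(length(values))
  if (!is.null(donor)) {
    use <- is.na(values) & !is.na(donor)
    values[use] <- donor[use]
    prov[use] <- 1L
  }
  if (anyNA(values)) {
    ok <- which(!is.na(values))
    if (length(ok) == 0L) stop("ridge empty: no pattern found in any band")
    na <- which(is.na(values))
    values[na] <- stats::approx(ok, values[ok], xout = na, rule = 2)$y
    prov[na] <- 2L
  }
  list(values = values, prov = prov)
}

#' Fit the oscillatory-pattern heart-rate model to a record
#'
#' The package's central estimator. The procedure: (1) estimate the
#' fundamental cardiac frequency `Fmain` from the full-record FFT; (2) form
#' the fundamental and double-harmonic bands about `Fmain`; (3) compute the
#' Morlet CWT energy surface on one grid covering both bands; (4) extract
#' per-time skeletons (local energy maxima) and link them into oscillatory
#' patterns with the epsilon-neighbourhood rule; (5) track the dominant
#' in-band pattern in each band; (6) emit the fundamental-band ridge as the
#' heart-rate series, with the harmonic-band ridge divided by two as an
#' independent consistency check and gap donor.
#'
#' @param record A [signal_record()].
#' @param config A [pipeline_config()].
#' @param keep_surface Keep the full CWT surface in the returned object
#'   (large; default `FALSE`).
#' @return Object of class `pattern_hr` with components `fmain`, `bands`,
#'   `fundamental`, `harmonic` (both [hr_series()], gap-filled),
#'   `reconciled` ([hr_series()]), `diagnostics` (gap fractions, per-sample
#'   fill provenance, fundamental-minus-half-harmonic difference trace),
#'   `config`, `record_info`, and optionally `surface`.
#' @seealso [reconcile()], [detect_rpeaks()] for the classical baseline.
#' @examples
#' \donttest{
#' cfg <- synth_config(duration = 120, seed = 7)
#' rec <- synthesize_ecg(synthesize_beats(generate_hr_truth(cfg)), cfg)
#' fit <- pattern_hr(rec)
#' summary(fit)
#' }
#' @export
pattern_hr <- function(record, config = pipeline_config(),
                       keep_surface = FALSE) {
  stopifnot(inherits(record, "signal_record"),
            inherits(config, "pipeline_config"))
  fmain <- estimate_fmain(record, config$fmain_range[1L], config$fmain_range[2L])
  bands <- make_bands(fmain, config$band_width)
  f_lo <- min(0.5, bands$fundamental$f_lo)
  f_hi <- bands$harmonic$f_hi
  grid <- frequency_grid(f_lo, f_hi, config$grid_step)
  surface <- compute_cwt(record, grid, config$decimation)
  frames <- extract_skeleton(surface, config$linking)
  patterns <- link_patterns(frames, config$linking)
  gr <- range(grid$freqs)
  rf <- dominant_ridge(patterns, bands$fundamental, surface$times, gr)
  rh <- dominant_ridge(patterns, bands$harmonic, surface$times, gr)
  if (all(rf$gap) && all(rh$gap))
    stop("empty ridge: no oscillatory pattern found in either band")

  half <- rh$freq / 2
  donor <- if (config$gap_fill == "harmonic") half else NULL
  ffill <- .fill_gaps(rf$freq, donor)
  hfill <- .fill_gaps(half, if (config$gap_fill == "harmonic") rf$freq else NULL)

  fs_out <- record$fs / config$decimation
  # edge flag of the output: cone of influence at the lowest band frequency
  M <- .cwt_halfwidth(bands$fundamental$f_lo, record$fs)
  idx <- seq.int(1L, length(record$samples), by = config$decimation)
  edge_out <- (idx <= M) | (idx > length(record$samples) - M)

  fund <- hr_series(rf$times, ffill$values, "pattern-fundamental",
                    fs_out = fs_out, gap = rf$gap, edge = edge_out)
  harm <- hr_series(rh$times, hfill$values, "pattern-harmonic",
                    fs_out = fs_out, gap = rh$gap, edge = edge_out)
  recd <- reconcile(fund, harm)

  gap_runs <- rle(rf$gap & !edge_out)
  longest_gap <- if (any(gap_runs$values))
    max(gap_runs$lengths[gap_runs$values]) / fs_out else 0
  if (longest_gap > config$max_gap_s)
    warning(sprintf("fundamental ridge gap of %.2f s exceeds max_gap_s = %g",
                    longest_gap, config$max_gap_s))

  out <- structure(list(
    fmain = fmain, bands = bands,
    fundamental = fund, harmonic = harm, reconciled = recd,
    diagnostics = list(
      gap_fraction_fundamental = mean(rf$gap),
      gap_fraction_harmonic = mean(rh$gap),
      longest_gap_s = longest_gap,
      fill_provenance = c("ridge", "harmonic", "interpolated")[ffill$prov + 1L],
      fund_minus_halfharm = ffill$values - hfill$values,
      n_patterns = length(patterns$patterns),
      n_skeleton_points = patterns$n_points),
    config = config,
    record_info = list(kind = record$kind, fs = record$fs,
                       n = length(record$samples), label = record$label)),
    class = "pattern_hr")
  if (keep_surface) out$surface <- surface
  out
}

#' Reconcile the fundamental ridge with the halved harmonic ridge
#'
#' Returns the fundamental heart-rate series with gap samples replaced by
#' the harmonic-derived value where one exists, and by linear interpolation
#' across the gap otherwise.
#'
#' @param fundamental,harmonic_halved Two [hr_series()] on identical time
#'   grids (the harmonic series already divided by two).
#' @return An [hr_series()] with provenance `"pattern-fundamental"` and no
#'   remaining gaps.
#' @export
reconcile <- function(fundamental, harmonic_halved) {
  stopifnot(inherits(fundamental, "hr_series"),
            inherits(harmonic_halved, "hr_series"))
  if (length(fundamental$times) != length(harmonic_halved$times) ||
      any(abs(fundamental$times - harmonic_halved$times) > 1e-9))
    stop("time grids of the two series do not match")
  v <- fundamental$values
  v[fundamental$gap] <- NA_real_
  donor <- harmonic_halved$values
  donor[harmonic_halved$gap] <- NA_real_
  fill <- .fill_gaps(v, donor)
  hr_series(fundamental$times, fill$values, "pattern-fundamental",
            fs_out = fundamental$fs_out,
            gap = rep(FALSE, length(v)), edge = fundamental$edge)
}

#' @export
print.pattern_hr <- function(x, ...) {
  cat("Oscillatory-pattern heart-rate fit\n")
  cat(sprintf("  input: %s, %d samples @ %g Hz (%.1f s)\n",
              x$record_info$kind, x$record_info$n, x$record_info$fs,
              x$record_info$n / x$record_info$fs))
  cat(sprintf("  Fmain = %.4f Hz; bands [%.3f, %.3f] / [%.3f, %.3f] Hz\n",
              x$fmain, x$bands$fundamental$f_lo, x$bands$fundamental$f_hi,
              x$bands$harmonic$f_lo, x$bands$harmonic$f_hi))
  v <- x$reconciled$values[!x$reconciled$edge]
  cat(sprintf("  HR: mean %.4f Hz (%.1f bpm) at %g Hz output rate; gaps %.1f%% / %.1f%%\n",
              mean(v), 60 * mean(v), x$fundamental$fs_out,
              100 * x$diagnostics$gap_fraction_fundamental,
              100 * x$diagnostics$gap_fraction_harmonic))
  invisible(x)
}

#' @export
summary.pattern_hr <- function(object, ...) {
  interior <- !object$reconciled$edge
  v <- object$reconciled$values[interior]
  d <- object$diagnostics$fund_minus_halfharm[interior]
  structure(list(
    fmain = object$fmain,
    bands = object$bands,
    fs_out = object$fundamental$fs_out,
    hr_mean = mean(v), hr_sd = stats::sd(v),
    hr_range = range(v),
    harmonic_mean_abs_diff = mean(abs(d), na.rm = TRUE),
    gap_fraction = object$diagnostics$gap_fraction_fundamental,
    n_patterns = object$diagnostics$n_patterns),
    class = "summary.pattern_hr")
}

#' @export
print.summary.pattern_hr <- function(x, ...) {
  cat("Oscillatory-pattern heart-rate fit\n")
  cat(sprintf("  Fmain              %.4f Hz\n", x$fmain))
  cat(sprintf("  fundamental band   [%.3f, %.3f] Hz\n",
              x$bands$fundamental$f_lo, x$bands$fundamental$f_hi))
  cat(sprintf("  harmonic band      [%.3f, %.3f] Hz\n",
              x$bands$harmonic$f_lo, x$bands$harmonic$f_hi))
  cat(sprintf("  output rate        %g Hz\n", x$fs_out))
  cat(sprintf("  HR mean (sd)       %.4f (%.4f) Hz = %.1f (%.1f) bpm\n",
              x$hr_mean, x$hr_sd, 60 * x$hr_mean, 60 * x$hr_sd))
  cat(sprintf("  HR range           [%.4f, %.4f] Hz\n",
              x$hr_range[1L], x$hr_range[2L]))
  cat(sprintf("  |fund - harm/2|    %.4f Hz mean (interior)\n",
              x$harmonic_mean_abs_diff))
  cat(sprintf("  ridge gaps         %.2f%%; %d patterns linked\n",
              100 * x$gap_fraction, x$n_patterns))
  invisible(x)
}

#' @export
fitted.pattern_hr <- function(object, ...) object$reconciled

#' @export
coef.pattern_hr <- function(object, ...) {
  c(fmain = object$fmain,
    band_lo = object$bands$fundamental$f_lo,
    band_hi = object$bands$fundamental$f_hi,
    hr_mean = mean(object$reconciled$values[!object$reconciled$edge]))
}

#' Residual trace of a pattern fit
#'
#' The per-sample difference between the fundamental-band ridge and half
#' the harmonic-band ridge — the model's internal consistency check. Near
#' zero when both bands track the same cardiac rhythm.
#'
#' @param object A `pattern_hr` fit.
#' @param ... Unused.
#' @return Numeric vector on the output time grid.
#' @export
residuals.pattern_hr <- function(object, ...) {
  object$diagnostics$fund_minus_halfharm
}

#' Predict heart rate at arbitrary times
#'
#' Linear interpolation of the reconciled heart-rate series.
#'
#' @param object A `pattern_hr` fit.
#' @param times Times in seconds within the fitted span.
#' @param ... Unused.
#' @return Numeric vector of heart rate in Hz.
#' @export
predict.pattern_hr <- function(object, times = NULL, ...) {
  s <- object$reconciled
  if (is.null(times)) return(s$values)
  if (any(times < min(s$times) - 1e-9) || any(times > max(s$times) + 1e-9))
    stop("prediction times outside the fitted span")
  stats::approx(s$times, s$values, xout = times)$y
}

#' @export
plot.pattern_hr <- function(x, ..., show_harmonic = TRUE) {
  s <- x$reconciled
  graphics::plot(s$times, s$values, type = "l", xlab = "time (s)",
                 ylab = "HR (Hz)", ...)
  if (show_harmonic)
    graphics::lines(x$harmonic$times, x$harmonic$values, col = "grey60",
                    lty = 2)
  graphics::abline(h = x$fmain, col = "grey80", lty = 3)
  graphics::legend("topright", bty = "n",
                   legend = c("fundamental ridge", "harmonic/2"),
                   col = c("black", "grey60"), lty = c(1, 2))
  invisible(x)
}

#' Detect heart rate (procedural interface)
#'
#' A thin wrapper around [pattern_hr()] returning the fundamental and
#' halved-harmonic series plus diagnostics, for callers that want the
#' pieces rather than the fitted object.
#'
#' @inheritParams pattern_hr
#' @return List with `fundamental`, `harmonic_halved`, `reconciled`
#'   ([hr_series()]) and `diagnostics`.
#' @export
detect_hr <- function(record, config = pipeline_config()) {
  fit <- pattern_hr(record, config)
  list(fundamental = fit$fundamental, harmonic_halved = fit$harmonic,
       reconciled = fit$reconciled, diagnostics = fit$diagnostics,
       fmain = fit$fmain, bands = fit$bands)
}
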