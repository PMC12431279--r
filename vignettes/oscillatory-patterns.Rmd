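---
title: "Continuous heart rate from ECG/PPG via wavelet oscillatory patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous heart rate from ECG/PPG via wavelet oscillatory patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
```

## The problem

The conventional way to measure heart rate (HR) from an ECG is contour
analysis: locate each R-peak, take the inter-beat interval $T_i$, and report
$\nu_i = 1/T_i$. This yields one HR value per beat — a *non-equidistant*
series at roughly 1 Hz — which must then be interpolated before any spectral
analysis of heart-rate variability (HRV). Contour analysis also degrades
badly when the waveform is deformed: arrhythmic QRS complexes, motion
artifacts during exercise, or inherently smooth photoplethysmogram (PPG)
pulses whose "peak" is far less sharp than an R-wave.

`wavehr` implements an alternative that never looks at waveform shape. The
cardiac rhythm appears in the time–frequency plane as a persistent ridge
near 1 Hz (and a second ridge at its double harmonic). Tracking that ridge
on a wavelet energy surface yields HR as a *continuous, equidistant* series
at one tenth of the signal sampling rate — 25 Hz for a 250 Hz recording —
regardless of waveform morphology.

## The method

### Wavelet energy surface

For a signal $x(t)$ sampled at $F_D$ Hz ($\Delta t = 1/F_D$), the package
computes the discretised Morlet continuous wavelet transform on a linear
grid of analysis frequencies $f$:

$$W(f, t_0) = f \, \Delta t \sum_t x(t)\, \psi^{*}\!\big(f (t - t_0)\big),
\qquad
\psi(\eta) = \pi^{-1/4} e^{2\pi j \eta} e^{-\eta^2/2},$$

and the energy surface $E(f, t_0) = |W(f, t_0)|^2$. The wavelet carries one
oscillation per unit $\eta$, so $f$ is read directly as frequency in Hz with
no centre-frequency correction.

Two numerical choices matter here:

* **Prefactor.** The transform is normalised with a *linear* prefactor $f$.
  At scale $1/f$ the wavelet's time support shrinks like $1/f$, so an
  $L^2$-style $\sqrt{f}$ normalisation leaves $|W| \propto f^{-1/2}$ along
  a tone's ridge and biases the energy argmax low by about $f/(8\pi^2)$
  ($\approx 0.013$ Hz at 1 Hz — two to three grid steps). The linear
  prefactor cancels that trend exactly: the energy ridge of a pure cosine
  peaks at the cosine's frequency to within grid resolution, which is the
  property the ridge tracker relies on.
* **Truncation and the cone of influence.** The infinite sum is truncated
  at $|\eta| \le 5$, where the Gaussian envelope is below $4\times10^{-6}$.
  Cells whose support window crosses a record edge are flagged
  edge-affected and excluded from ridge selection and from discrepancy
  statistics; at the default 0.8 Hz band edge this is the first and last
  6.25 s of a recording.

The FFT-convolution implementation is checked in the test suite against a
literal direct-sum evaluation (`cwt_direct()`); they agree to better than
$10^{-9}$ relative error outside edge regions.

### Skeletons and oscillatory patterns

At each analysis time the *skeleton* is the set of strict interior local
maxima of $E(\cdot, t)$ along the frequency axis (zero first derivative,
negative second derivative on the discrete grid). At most `max_skeletons`
(default 25) maxima are kept per time, highest energy first. Exact-tie
plateaus — a floating-point corner case the derivative definition does not
cover — count once, at their leftmost cell, and only if the energy drops on
both sides.

Skeleton points are then chained across consecutive analysis times into
*oscillatory patterns*: a point at time $t_{k+1}$ extends a pattern whose
frequency at $t_k$ lies within $\varepsilon$ (default 0.04 Hz, i.e. ten
sampling periods of a 250 Hz recording). The chaining rule the package
fixes where the method description leaves freedom:

* candidate (pattern, point) pairs are processed by ascending frequency
  distance, ties broken toward the lower frequency;
* each pattern extends at most once per step and each point joins at most
  one pattern (greedy nearest-first matching — deterministic and
  order-independent after sorting);
* unmatched points open new patterns; a pattern with no continuation
  terminates. Patterns never merge, split, or span gaps.

### From patterns to heart rate

The pipeline (`pattern_hr()`) runs six steps:

1. record the signal (any of ECG, PPG, differentiated PPG);
2. estimate the fundamental frequency `Fmain` as the dominant peak of the
   full-record amplitude spectrum in the search range (default 0.5–2 Hz),
   with a subharmonic guard: ECG spectra are harmonic-rich, and if a peak
   near half the argmax holds at least 40% of its amplitude, that
   subharmonic is the true fundamental;
3. compute one energy surface covering both analysis bands;
4. extract skeletons and link patterns;
5. form the fundamental band $[F_\mathrm{main}(1-w),\,F_\mathrm{main}(1+w)]$
   (default $w = 0.2$, giving $[0.8, 1.2]$ Hz at 1 Hz) and the double-harmonic
   band, the same relative window about $2F_\mathrm{main}$ ($[1.6, 2.4]$ Hz);
6. in each band report, per time, the frequency of the pattern with the
   greatest cumulative in-band energy; the harmonic ridge divided by two is
   an independent second estimate.

Which pattern should supply the ridge when several coexist in-band is not
prescribed by the method description; the cumulative-energy rule is this
package's choice, validated against synthetic ground truth (the dominant
cardiac pattern accumulates energy over minutes, noise patterns over
seconds).

Ridge gaps — times where no in-band pattern point exists — are filled by
the halved harmonic ridge where it is available, and by linear
interpolation otherwise (`reconcile()`); fills are recorded per sample in
the diagnostics, and a gap longer than `max_gap_s` (default 2 s) raises a
warning. The per-time difference between the fundamental and halved
harmonic ridges is kept as the fit's residual trace: it is the model's
internal consistency check and should sit near zero on clean recordings.

### Parameters at a glance

| parameter | default | units | why |
|---|---|---|---|
| `grid_step` | 0.005 | Hz | ~80–160 bins per band: resolution vs cost |
| `decimation` | 10 | samples | output HR rate $F_D/10$ (25 Hz at 250 Hz) |
| `epsilon` | 0.04 | Hz | $10\,\Delta_D$ at 250 Hz; max ridge drift per step |
| `max_skeletons` | 25 | – | cap on per-time maxima |
| `band_width` | 0.2 | – | ±20% about `Fmain` and `2*Fmain` |
| `fmain_range` | 0.5–2.0 | Hz | 30–120 bpm; widen for tachycardic signals |
| `max_gap_s` | 2 | s | longest silent ridge before a warning |

The tolerance `epsilon` is dimensionally a frequency: it bounds how far the
tracked component may move along the frequency axis between consecutive
analysis times, and it is compared against skeleton frequencies.

## The classical baseline

`detect_rpeaks()` implements the classical contour detector the wavelet
method is compared against: 5–15 Hz zero-phase band-pass, differentiation,
squaring, 150 ms moving-window integration, adaptive dual thresholds with a
0.25 s refractory period, and refinement of each detection to the local
band-passed maximum. For PPG the same adaptive logic runs on the 0.5–8 Hz
pulse wave directly. `annotations_to_hr()` converts beat indices to
$\nu = 1/T$ at interval midpoints, and `to_equidistant()` interpolates
(linear by default, stepwise optionally) onto a uniform grid.

This recipe is a documented stand-in for "the traditional R-peak method":
the classical literature describes a family of such detectors rather than
one canonical parameterisation, so its outputs are *compared*, never
claimed identical to any particular implementation.

## Agreement statistics and HRV indices

Two HR series are aligned by linear resampling to the finer of their grids
over the overlapping span (the methods under comparison have different
native rates: 25 Hz for the pattern method, ~1 Hz for beat-by-beat HR).
On the common grid the package reports mean/SD per series, the mean
absolute difference, Bland–Altman limits of agreement
$\bar d \pm 1.96\,s_d$ with standard confidence intervals
($\mathrm{SE}(\bar d) = s_d/\sqrt n$,
$\mathrm{SE}(\mathrm{LoA}) = s_d\sqrt{3/n}$), the percentage of differences
outside the limits, and the maximum relative discrepancy
$100\max_i |a_i - b_i|/b_i$ with edge-affected samples excluded.

Spectral HRV indices use the amplitude spectrum (not power) of the
mean-removed, Hann-tapered HR series: band amplitudes are summed within
VLF [0.0033, 0.04), LF [0.04, 0.15) and HF [0.15, 0.4] Hz, normalised by
the three-band total (so the normalised indices always sum to 1), and
LF/HF is the ratio of the raw LF and HF amplitudes. Amplitudes rather than
powers are used because the quantity of interest here is the relative
amplitude of slow and fast autonomic modulation. At least 125 s of data is
needed before the LF band is meaningfully resolved; shorter series trigger
a warning.

Mean, SD and mean-absolute-difference are the package's reading of the
summary statistics used in the reference analyses (arithmetic mean, sample
SD with $n-1$, mean absolute pointwise difference on the common grid);
where the original formula set is not available this interpretation is the
documented contract.

## The synthetic generator

Every claim in the test suite is validated against `synth_config()` /
`simulate_record()` signals with *exact* ground truth:

* the true rate is
  $HR(t) = \bar\nu + a_\mathrm{LF}\sin(2\pi f_\mathrm{LF} t)
  + a_\mathrm{HF}\sin(2\pi f_\mathrm{HF} t) + j(t)$, with defaults
  $\bar\nu = 1$ Hz, $a_\mathrm{LF} = a_\mathrm{HF} = 0.03$ Hz at 0.1 and
  0.3 Hz, and $j(t)$ seeded white noise low-passed at 0.4 Hz and scaled to
  0.01 Hz SD — a resting adult with modest autonomic modulation whose rate
  content stays inside the standard HRV bands;
* beats are placed by integrate-and-fire: beat times are the integer
  crossings of $\int_0^t HR(\tau)\,d\tau$, so the rate between consecutive
  beats integrates to exactly one cycle and the ground truth is exact by
  construction rather than approximated from stacked periods;
* ECG beats are sharp biphasic QRS templates (8 ms Gaussian R-wave with Q/S
  dips, plus small P and T bumps); PPG beats are smooth asymmetric pulses
  (~0.15 s rise, ~0.45 s decay, dicrotic bump), with a first-difference
  PPGd variant;
* corruption adds seeded white noise at a prescribed SNR, optional baseline
  wander (off by default, so the default configuration is exactly clean),
  and band-limited 5–15 Hz bursts inside motion-artifact windows, tapered
  at the window edges.

The templates are deliberately minimal — no full dynamical ECG model. The
method under test uses only the near-1 Hz periodicity and its harmonics,
and the robustness claims concern noise, not morphology fidelity. Passing
tests therefore demonstrate rate *tracking* under noise and artifacts; they
do not certify behaviour on pathological morphologies (atrial fibrillation,
bigeminy), which the generator does not simulate.

## Validation conditions and known limitations

The long-run validation uses 600 s records at 250 Hz: a clean ECG with
$HR(t) = 1 + 0.1\sin(2\pi\,0.1t)$ Hz for rate recovery (fundamental-ridge
RMSE vs truth ≤ 0.02 Hz on the interior 80%), and a PPG at 0 dB SNR with
two 30 s artifact bursts for robustness (pattern-method maximum relative
error below 5% at interior times while the R-peak baseline fails by an
order of magnitude inside the artifact windows). Shorter records (60–300 s)
cover unit-level properties. `scripts/acceptance.R` re-runs these
computations from scratch.

Known limitations, inherent to the construction:

* **Ridge smoothing.** The wavelet at frequency $f$ averages over a
  Gaussian window of SD $1/f$ seconds, so rate modulation at frequency
  $f_m$ is attenuated by roughly $\exp(-2(\pi f_m/f)^2)$: ~18% of the
  amplitude at $f_m = 0.1$ Hz is lost, and HF modulation near 0.3 Hz is
  attenuated heavily on the fundamental ridge (less so on the harmonic
  ridge, whose window is half as long). The HR trace is correspondingly
  smoother than beat-to-beat truth, and maximum-error statistics against a
  jittery truth sit near the attenuation floor rather than at zero.
* **Frequency quantisation.** Ridge values live on the 0.005 Hz grid;
  sub-grid refinement is deliberately not applied so that the skeleton and
  pattern containers stay exact grid objects.
* **Band capture.** If the true rate leaves
  $[F_\mathrm{main}(1-w), F_\mathrm{main}(1+w)]$ — a sprint pushing HR
  from 60 to 120 bpm — the fundamental ridge goes silent and only the
  harmonic/gap machinery covers the excursion; `band_width` and
  `fmain_range` must be widened for strongly non-stationary protocols.
* **No streaming.** The fundamental estimate uses the whole record, and the
  FFT convolution is batch; real-time operation is out of scope.

## Worked example

```{r example, eval = FALSE}
library(wavehr)

cfg <- synth_config(duration = 300, seed = 42)
sim <- simulate_record(cfg)

fit <- pattern_hr(sim$record)
summary(fit)

# agreement with the classical baseline
rp <- to_equidistant(annotations_to_hr(detect_rpeaks(sim$record), cfg$fs),
                     fs_out = 25)
bland_altman(fitted(fit), rp)

# HRV spectral indices of the continuous HR trace
spectral_indices(fitted(fit))
```
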