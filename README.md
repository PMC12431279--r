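# wavehr

Continuous heart-rate estimation from ECG and PPG signals by tracking
oscillatory patterns on a Morlet wavelet energy surface — plus a classical
R-peak baseline, Bland–Altman agreement statistics, LF/HF spectral indices
of heart-rate variability, and a seeded synthetic generator with exact
ground-truth rate.

## Why

Conventional heart-rate analysis is contour-based: find each R-peak, take
the inter-beat interval `T`, report `ν = 1/T`. That gives one value per
beat — a non-equidistant series near 1 Hz that must be interpolated before
any HRV spectral analysis — and it breaks down when the waveform is
deformed: arrhythmia, motion artifacts during walking, or smooth PPG pulses
with no sharp fiducial point.

`wavehr` instead treats the cardiac rhythm as a ridge in the time–frequency
plane. It computes the Morlet continuous wavelet transform

    W(f, t0) = f·Δt·Σ_t x(t)·ψ*(f(t − t0)),   ψ(η) = π^(−1/4)·e^(2πjη)·e^(−η²/2)

and the energy surface `E(f, t0) = |W(f, t0)|²`, extracts per-time local
maxima of `E` ("skeletons", at most 25 per time), links them across time
into oscillatory patterns whenever consecutive frequencies stay within
ε = 0.04 Hz, and follows the dominant pattern inside the fundamental
cardiac band `[Fmain·0.8, Fmain·1.2]` (and, as a consistency check, inside
the double-harmonic band `[2·Fmain·0.8, 2·Fmain·1.2]`). The result is an
equidistant instantaneous HR series in Hz at one tenth of the signal
sampling rate — 25 Hz for a 250 Hz recording — independent of waveform
shape, which is why the same pipeline handles ECG, PPG and even
differentiated PPG, and keeps working through motion-artifact bursts that
defeat the R-peak detector.

## Worked example

```r
library(wavehr)

# 300 s synthetic ECG, 250 Hz, resting rate 1 Hz with LF/HF modulation
cfg <- synth_config(duration = 300, seed = 42)
sim <- simulate_record(cfg)

fit <- pattern_hr(sim$record)
summary(fit)
#> Oscillatory-pattern heart-rate fit
#>   Fmain              1.0000 Hz
#>   fundamental band   [0.800, 1.200] Hz
#>   harmonic band      [1.600, 2.400] Hz
#>   output rate        25 Hz
#>   HR mean (sd)       0.9997 (0.0188) Hz = 60.0 (1.1) bpm
#>   HR range           [0.9650, 1.0350] Hz
#>   |fund - harm/2|    0.0110 Hz mean (interior)
#>   ridge gaps         3.31%; 115 patterns linked
```

`Fmain` is the dominant spectral frequency of the whole record (the mean
heart rate, here 60 bpm); the two bands are where the fundamental and
second-harmonic ridges are tracked; `|fund − harm/2|` is the fit's internal
consistency residual — the two bands independently estimate the same
rhythm, so a mean difference of ~0.01 Hz says the ridge is trustworthy.

Agreement with the classical R-peak baseline on the same record:

```r
rp <- to_equidistant(annotations_to_hr(detect_rpeaks(sim$record), cfg$fs),
                     fs_out = 25)
bland_altman(fitted(fit), rp)
#> Bland-Altman agreement report
#>   n aligned          7431
#>   mean (sd) a        0.9996 (0.0188) Hz
#>   mean (sd) b        0.9996 (0.0257) Hz
#>   mean |a-b|         0.01045 Hz
#>   mean diff [CI]     0.00005 [-0.00023, 0.00033] Hz
#>   limits of agreement [-0.02409, 0.02420] Hz
#>   outside limits     3.08%
#>   max rel discrepancy 3.509%
```

The mean difference between methods is ~5×10⁻⁵ Hz with limits of agreement
of ±0.024 Hz (±1.4 bpm): the wavelet trace and the beat-by-beat trace
measure the same rhythm, the wavelet one smoother (SD 0.019 vs 0.026 Hz)
because ridge tracking attenuates the fastest rate fluctuations.

```r
spectral_indices(fitted(fit))
#> <spectral_indices> VLF 0.0885  LF 0.6427  HF 0.2688 (normalised); LF/HF = 2.3907
```

LF/HF > 1 here reflects the ridge smoothing: the generator injected equal
LF and HF rate amplitudes, and the HF component is attenuated more. See the
vignette (`vignettes/oscillatory-patterns.Rmd`) for the attenuation model
and all tunable parameters.

## Command line

A thin CLI ships in `exec/wavehr`:

```sh
wavehr simulate --duration 600 --seed 42 --kind ecg --out rec.csv --truth-out truth.csv
wavehr detect   --input rec.csv --format csv --fs 250 --out hr.csv
wavehr rpeaks   --input rec.csv --format csv --fs 250 --out ann.csv --fs-out 25
wavehr compare  --a hr.csv --b truth.csv --report report.json
wavehr hrv      --input hr.csv --out indices.json
```

Input formats: CSV (sampling rate via `--fs`), WFDB (`.hea`/`.dat`,
formats 16 and 212, `.atr` beat annotations) and EDF.

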