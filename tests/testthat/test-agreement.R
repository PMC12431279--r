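mk <- function(values, fs = 25, t0 = 0, prov = "truth", edge = NULL) {
  hr_series(t0 + (seq_along(values) - 1) / fs, values, prov, edge = edge)
}

test_that("summary statistics are the arithmetic mean and sample SD", {
  expect_equal(hr_summary_stats(mk(rep(1, 10))), c(mean = 1, sd = 0))
  expect_equal(hr_summary_stats(mk(c(0.9, 1.1))),
               c(mean = 1, sd = sd(c(0.9, 1.1))))
})

test_that("mean absolute difference aligns series and is symmetric", {
  a <- mk(c(1.0, 1.2))
  b <- mk(c(1.1, 1.0))
  expect_equal(mean_abs_diff(a, b), 0.15)
  expect_equal(mean_abs_diff(a, a), 0)
  off <- mk(c(1.0, 1.2) + 0.05)
  expect_equal(mean_abs_diff(a, off), 0.05)
  expect_equal(mean_abs_diff(a, b), mean_abs_diff(b, a))
  # different native rates: resampled to the finer grid over the overlap
  fine <- mk(rep(1, 101), fs = 25)
  coarse <- mk(rep(1.2, 5), fs = 1)
  expect_equal(mean_abs_diff(fine, coarse), 0.2, tolerance = 1e-12)
  late <- mk(rep(1, 10), t0 = 100)
  expect_error(mean_abs_diff(a, late), "overlap")
})

test_that("Bland-Altman limits behave on degenerate and constant differences", {
  a <- mk(seq(1, 1.2, length.out = 50))
  rep0 <- bland_altman(a, a)
  expect_equal(rep0$ba_mean_diff, 0)
  expect_equal(rep0$ba_loa_lo, 0)
  expect_equal(rep0$ba_loa_hi, 0)
  expect_equal(rep0$pct_outside_loa, 0)

  b <- mk(seq(1, 1.2, length.out = 50) - 0.001)
  rep1 <- bland_altman(a, b)
  expect_equal(rep1$ba_mean_diff, 0.001, tolerance = 1e-12)
  expect_equal(rep1$ba_loa_hi - rep1$ba_loa_lo, 0, tolerance = 1e-12)
  expect_error(bland_altman(mk(c(1, 1)), mk(c(1, 1))), "3 aligned")
})

test_that("about 5% of iid normal differences fall outside the limits", {
  set.seed(99)
  n <- 10000
  d <- rnorm(n, 0, 0.05)
  a <- mk(1 + d, fs = 25)
  b <- mk(rep(1, n), fs = 25)
  rep <- bland_altman(a, b)
  expect_lt(abs(rep$pct_outside_loa - 5), 0.6)
  # antisymmetry under swapping the series
  rep_sw <- bland_altman(b, a)
  expect_equal(rep_sw$ba_mean_diff, -rep$ba_mean_diff, tolerance = 1e-12)
  expect_equal(rep_sw$ba_loa_lo, -rep$ba_loa_hi, tolerance = 1e-12)
  expect_equal(rep_sw$ba_loa_hi, -rep$ba_loa_lo, tolerance = 1e-12)
})

test_that("maximum relative discrepancy uses b as reference, excluding edges", {
  a <- mk(c(1.0, 1.2))
  expect_equal(max_rel_discrepancy(a, a), 0)
  b5 <- mk(1.05 * c(1.0, 1.2))
  expect_equal(max_rel_discrepancy(b5, a), 5, tolerance = 1e-9)
  x <- mk(c(1.0, 1.2)); y <- mk(c(1.0, 1.25))
  expect_equal(max_rel_discrepancy(x, y), 4, tolerance = 1e-9)
  # edge samples excluded
  e <- mk(c(9, 1.0, 1.2, 9), edge = c(TRUE, FALSE, FALSE, TRUE))
  r <- mk(c(1.0, 1.0, 1.2, 1.2), edge = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(max_rel_discrepancy(e, r), 0, tolerance = 1e-9)
})

test_that("agreement statistics scale correctly under a common factor", {
  set.seed(4)
  a <- mk(1 + rnorm(200, 0, 0.03))
  b <- mk(1 + rnorm(200, 0, 0.03))
  ca <- mk(2 * a$values); cb <- mk(2 * b$values)
  expect_equal(mean_abs_diff(ca, cb), 2 * mean_abs_diff(a, b), tolerance = 1e-12)
  r1 <- bland_altman(a, b); r2 <- bland_altman(ca, cb)
  expect_equal(r2$ba_mean_diff, 2 * r1$ba_mean_diff, tolerance = 1e-12)
  expect_equal(r2$ba_loa_hi, 2 * r1$ba_loa_hi, tolerance = 1e-12)
  expect_equal(max_rel_discrepancy(ca, cb), max_rel_discrepancy(a, b),
               tolerance = 1e-9)
})

test_that("spectral indices resolve LF and HF modulation and normalise to 1", {
  fs <- 25
  t <- seq(0, 600, by = 1 / fs)
  hr <- mk(1 + 0.05 * sin(2 * pi * 0.1 * t) + 0.05 * sin(2 * pi * 0.3 * t),
           fs = fs)
  si <- spectral_indices(hr)
  expect_equal(si$vlf_n + si$lf_n + si$hf_n, 1, tolerance = 1e-9)
  expect_lt(abs(si$lf_n - si$hf_n) / si$lf_n, 0.05)

  hr2 <- mk(1 + 0.05 * sin(2 * pi * 0.1 * t) + 0.10 * sin(2 * pi * 0.3 * t),
            fs = fs)
  si2 <- spectral_indices(hr2)
  expect_lt(abs(si2$lf_hf - 0.5) / 0.5, 0.10)

  # pure VLF modulation
  hr3 <- mk(1 + 0.05 * sin(2 * pi * 0.01 * t), fs = fs)
  si3 <- spectral_indices(hr3)
  expect_gt(si3$vlf_n, 0.95)
  expect_lt(si3$lf_n + si3$hf_n, 0.05)

  expect_error(spectral_indices(mk(rep(1, 1000))), "constant")
  # scale invariance of the normalised indices
  si_scaled <- spectral_indices(mk(2 * hr$values, fs = fs))
  expect_equal(si_scaled$lf_n, si$lf_n, tolerance = 1e-9)
  expect_equal(si_scaled$lf_hf, si$lf_hf, tolerance = 1e-9)
})
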