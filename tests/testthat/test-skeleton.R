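# brute-force oracle for the discrete local-maximum definition
oracle_maxima <- function(v) {
  out <- integer(0)
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) out <- c(out, i)
    # leftmost cell of an exact-tie plateau that descends on both sides
    if (v[i] > v[i - 1] && v[i] == v[i + 1]) {
      j <- i
      while (j < length(v) && v[j + 1] == v[i]) j <- j + 1
      if (j < length(v) && v[j + 1] < v[i]) out <- c(out, i)
    }
  }
  sort(unique(out))
}

make_surface <- function(E, freqs, times) {
  structure(list(times = times, freqs = freqs, W = NULL, E = E,
                 edge = matrix(FALSE, nrow(E), ncol(E)),
                 decimation = 1L, fs = 1),
            class = "tf_surface")
}

test_that("skeleton extraction finds exactly the strict interior maxima", {
  E <- rbind(c(1, 3, 2, 5, 4),
             c(1, 2, 3, 4, 5),
             c(5, 4, 3, 2, 1),
             c(1, 4, 4, 4, 1),
             c(2, 1, 2, 1, 2))
  s <- make_surface(E, freqs = 1:5, times = 0:4)
  fr <- extract_skeleton(s, linking_params(epsilon = 1))
  expect_equal(sort(fr[[1]]$sc), c(2, 4))        # [1,3,2,5,4]
  expect_equal(fr[[1]]$sc[1], 4)                 # sorted by descending energy
  expect_length(fr[[2]]$sc, 0)                   # monotone: no maxima
  expect_length(fr[[3]]$sc, 0)
  expect_equal(fr[[4]]$sc, 2)                    # plateau counts once, leftmost
  expect_equal(fr[[5]]$sc, 3)                    # endpoints never reported

  # randomized check against the oracle
  set.seed(42)
  for (rep in 1:50) {
    v <- sample(0:5, 31, replace = TRUE) + runif(31) * sample(0:1, 31, TRUE)
    got <- extract_skeleton(make_surface(rbind(v), seq_along(v), 0),
                            linking_params(epsilon = 1))[[1]]
    expect_equal(sort(match(got$sc, seq_along(v))), oracle_maxima(v))
  }
})

test_that("skeleton cap keeps the highest-energy maxima", {
  # 30 distinct peaks with distinct heights
  set.seed(1)
  heights <- sample(seq(1, 30) + 0.1)
  v <- rep(0, 61)
  v[seq(2, 60, by = 2)] <- heights
  s <- make_surface(rbind(v), seq_along(v), 0)
  fr <- extract_skeleton(s, linking_params(max_skeletons = 25))[[1]]
  expect_length(fr$sc, 25)
  expect_equal(sort(fr$E), sort(sort(heights, decreasing = TRUE)[1:25]))
})

test_that("epsilon-linking chains points and terminates across gaps", {
  mkframes <- function(...) {
    scs <- list(...)
    lapply(seq_along(scs), function(k) {
      sc <- scs[[k]]
      list(t = k - 1, sc = sc, E = rep(1, length(sc)),
           edge = rep(FALSE, length(sc)))
    })
  }
  p <- link_patterns(mkframes(1.00, 1.01, 1.30), linking_params(0.04))
  expect_length(p$patterns, 2)
  lens <- sort(vapply(p$patterns, function(q) length(q$t), integer(1)))
  expect_equal(lens, c(1L, 2L))
  chain <- p$patterns[[which(vapply(p$patterns, function(q) length(q$t),
                                    integer(1)) == 2)]]
  expect_equal(chain$sc, c(1.00, 1.01))

  # empty frame terminates all active patterns
  p2 <- link_patterns(mkframes(1.00, numeric(0), 1.00), linking_params(0.04))
  expect_length(p2$patterns, 2)
  expect_true(all(vapply(p2$patterns, function(q) length(q$t), integer(1)) == 1))

  # nearest-first greedy assignment: 0.98 extends, 1.03 starts new
  p3 <- link_patterns(mkframes(1.00, c(0.98, 1.03)), linking_params(0.04))
  expect_length(p3$patterns, 2)
  ext <- p3$patterns[[which(vapply(p3$patterns, function(q) length(q$t),
                                   integer(1)) == 2)]]
  expect_equal(ext$sc, c(1.00, 0.98))
})

test_that("linking partitions all skeleton points and respects epsilon", {
  set.seed(5)
  frames <- lapply(0:99, function(k) {
    m <- sample(0:5, 1)
    sc <- sort(runif(m, 0.5, 2.5))
    list(t = k * 0.04, sc = sc, E = runif(m), edge = rep(FALSE, m))
  })
  params <- linking_params(epsilon = 0.04)
  p <- link_patterns(frames, params)
  n_in <- sum(vapply(frames, function(f) length(f$sc), integer(1)))
  n_out <- sum(vapply(p$patterns, function(q) length(q$t), integer(1)))
  expect_equal(n_out, n_in)          # partition property
  expect_equal(p$n_points, n_in)
  for (q in p$patterns) {
    if (length(q$sc) > 1) {
      expect_true(all(abs(diff(q$sc)) <= params$epsilon + 1e-12))
      expect_equal(diff(q$t), rep(0.04, length(q$t) - 1), tolerance = 1e-9)
    }
  }
  # determinism
  p2 <- link_patterns(frames, params)
  expect_identical(as.data.frame(p), as.data.frame(p2))
})

test_that("dominant ridge follows the highest-cumulative-energy pattern", {
  mkpat <- function(id, t, sc, E) list(id = id, t = t, sc = sc, E = E,
                                       edge = rep(FALSE, length(t)),
                                       duration = max(t) - min(t),
                                       cum_energy = sum(E))
  times <- seq(0, 0.9, by = 0.1)
  ps <- structure(list(patterns = list(
    mkpat(1L, times, rep(1.0, 10), rep(10, 10)),
    mkpat(2L, times, rep(1.1, 10), rep(2, 10))), n_points = 20L),
    class = "pattern_set")
  band <- band_spec(0.8, 1.2, "fundamental")
  r <- dominant_ridge(ps, band, times)
  expect_equal(r$freq, rep(1.0, 10))
  expect_false(any(r$gap))

  # all patterns outside the band: all gaps
  r2 <- dominant_ridge(ps, band_spec(3, 4, "harmonic"), times,
                       grid_range = c(0.5, 5))
  expect_true(all(r2$gap))
  expect_error(dominant_ridge(ps, band_spec(3, 4), times,
                              grid_range = c(0.5, 2.4)), "outside")
})

test_that("linked ridge tracks a noise-free chirp within one grid step", {
  fs <- 250
  dur <- 300
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  f_inst <- 0.9 + 0.2 * t / dur                  # linear chirp 0.9 -> 1.1 Hz
  phase <- 2 * pi * cumsum(f_inst) / fs
  rec <- signal_record(cos(phase), fs)
  g <- frequency_grid(0.5, 1.5, 0.005)
  s <- compute_cwt(rec, g, 25L)
  frames <- extract_skeleton(s, linking_params())
  pats <- link_patterns(frames, linking_params())
  lens <- vapply(pats$patterns, function(q) length(q$t), integer(1))
  main <- pats$patterns[[which.max(lens)]]
  ok <- !main$edge
  truth <- 0.9 + 0.2 * main$t[ok] / dur
  expect_true(all(abs(main$sc[ok] - truth) <= 0.005 + 1e-9))
})
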