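#' Linking parameters for skeleton tracking
#'
#' @param epsilon Frequency tolerance in Hz for chaining skeleton points
#'   across consecutive analysis times. The default 0.04 Hz equals ten
#'   sampling periods of a 250 Hz recording (10/250).
#' @param max_skeletons Maximum number of local maxima retained per time
#'   column (highest-energy first); default 25.
#' @return Object of class `linking_params`.
#' @export
linking_params <- function(epsilon = 0.04, max_skeletons = 25L) {
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0))
    stop("'epsilon' must be a single positive number (Hz)")
  max_skeletons <- as.integer(max_skeletons)
  if (max_skeletons < 1L) stop("'max_skeletons' must be >= 1")
  structure(list(epsilon = epsilon, max_skeletons = max_skeletons),
            class = "linking_params")
}

#' Extract the skeleton of an energy surface
#'
#' At each analysis time the skeleton is the set of strict interior local
#' maxima of the energy `E(f, t)` along the frequency axis (zero first
#' derivative, negative second derivative on the discrete grid:
#' `E[i-1] < E[i] > E[i+1]`; an exact-tie plateau counts once, at its
#' leftmost cell). If a column has more maxima than `max_skeletons`, the
#' highest-energy ones are kept. Grid endpoints are never reported.
#'
#' @param surface A `tf_surface` from [compute_cwt()].
#' @param params A [linking_params()].
#' @return A list of skeleton frames, one per analysis time: each a list
#'   with `t` (s), `sc` (frequencies in Hz, sorted by descending energy),
#'   `E` (energies), `edge` (logical, cone-of-influence flag per point).
#' @export
extract_skeleton <- function(surface, params = linking_params()) {
  stopifnot(inherits(surface, "tf_surface"), inherits(params, "linking_params"))
  nf <- length(surface$freqs)
  if (nf < 3L) stop("skeleton extraction needs at least 3 grid frequencies")
  lapply(seq_along(surface$times), function(i) {
    col <- surface$E[i, ]
    ix <- local_maxima(col)
    if (length(ix) > params$max_skeletons)
      ix <- ix[order(col[ix], decreasing = TRUE)[seq_len(params$max_skeletons)]]
    ord <- order(col[ix], decreasing = TRUE)
    ix <- ix[ord]
    list(t = surface$times[i], sc = surface$freqs[ix], E = col[ix],
         edge = surface$edge[i, ix])
  })
}

#' Link skeleton frames into oscillatory patterns
#'
#' Chains skeleton points across consecutive analysis times: a point at
#' time `t[k+1]` extends an active pattern when its frequency falls within
#' `epsilon` of the pattern's frequency at time `t[k]`. When several
#' (pattern, point) pairings are admissible, pairs are processed by
#' ascending frequency distance (ties toward the lower point frequency,
#' then the lower pattern-head frequency); each pattern is extended at most
#' once and each point is used at most once. Unmatched points start new
#' patterns; a pattern that finds no continuation terminates — patterns
#' never merge, split, or span gaps.
#'
#' @param frames Skeleton frames from [extract_skeleton()], chronological.
#' @param params A [linking_params()].
#' @return Object of class `pattern_set`: list with `patterns` (a list,
#'   each with `id`, `t`, `sc`, `E`, `edge`, `duration`, `cum_energy`) and
#'   `n_points` (total points linked).
#' @export
link_patterns <- function(frames, params = linking_params()) {
  stopifnot(inherits(params, "linking_params"))
  eps <- params$epsilon
  patterns <- list()          # closed patterns
  active <- list()            # each: list(t=, sc=, E=, edge=) growing vectors
  n_pts_total <- 0L
  next_id <- 1L

  close_pattern <- function(p) {
    p$id <- next_id
    next_id <<- next_id + 1L
    p$duration <- p$t[length(p$t)] - p$t[1L]
    p$cum_energy <- sum(p$E)
    patterns[[length(patterns) + 1L]] <<- p
  }

  for (fr in frames) {
    m <- length(fr$sc)
    n_pts_total <- n_pts_total + m
    if (length(active) == 0L) {
      if (m > 0L)
        active <- lapply(seq_len(m), function(j)
          list(t = fr$t, sc = fr$sc[j], E = fr$E[j], edge = fr$edge[j]))
      next
    }
    heads <- vapply(active, function(p) p$sc[length(p$sc)], numeric(1))
    if (m == 0L) {
      for (p in active) close_pattern(p)
      active <- list()
      next
    }
    # candidate (pattern, point) pairs within epsilon, greedy nearest-first
    d <- abs(outer(heads, fr$sc, "-"))
    cand <- which(d <= eps, arr.ind = TRUE)
    pat_used <- rep(FALSE, length(active))
    pt_used <- rep(FALSE, m)
    if (nrow(cand) > 0L) {
      dd <- d[cand]
      ord <- order(dd, fr$sc[cand[, 2L]], heads[cand[, 1L]])
      for (r in ord) {
        pi <- cand[r, 1L]; qi <- cand[r, 2L]
        if (pat_used[pi] || pt_used[qi]) next
        pat_used[pi] <- TRUE; pt_used[qi] <- TRUE
        p <- active[[pi]]
        p$t <- c(p$t, fr$t); p$sc <- c(p$sc, fr$sc[qi])
        p$E <- c(p$E, fr$E[qi]); p$edge <- c(p$edge, fr$edge[qi])
        active[[pi]] <- p
      }
    }
    # terminate unextended patterns, open new ones for unmatched points
    for (pi in which(!pat_used)) close_pattern(active[[pi]])
    active <- active[pat_used]
    for (qi in which(!pt_used))
      active[[length(active) + 1L]] <-
        list(t = fr$t, sc = fr$sc[qi], E = fr$E[qi], edge = fr$edge[qi])
  }
  for (p in active) close_pattern(p)
  structure(list(patterns = patterns, n_points = n_pts_total),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  durs <- vapply(x$patterns, function(p) length(p$t), integer(1))
  cat(sprintf("<pattern_set> %d patterns, %d skeleton points (longest %d steps)\n",
              length(x$patterns), x$n_points,
              if (length(durs)) max(durs) else 0L))
  invisible(x)
}

#' Export a pattern set as a long data frame
#'
#' @param x A `pattern_set`.
#' @param ... Unused.
#' @return Data frame with columns `pattern_id`, `t`, `sc_hz`, `energy`, `edge`.
#' @export
as.data.frame.pattern_set <- function(x, ...) {
  do.call(rbind, lapply(x$patterns, function(p)
    data.frame(pattern_id = p$id, t = p$t, sc_hz = p$sc, energy = p$E,
               edge = p$edge)))
}

#' Dominant in-band ridge of a pattern set
#'
#' For each analysis time, reports the frequency of the admissible pattern
#' with the greatest cumulative in-band energy among patterns covering that
#' time, restricted to points inside the band and outside the cone of
#' influence. Times with no admissible point are flagged as gaps (to be
#' filled downstream).
#'
#' @param patterns A `pattern_set` from [link_patterns()].
#' @param band A [band_spec()].
#' @param times Analysis-time vector of the underlying surface.
#' @param grid_range Optional numeric length-2 range of the surface's
#'   frequency grid; when supplied, a band wholly outside it is an error.
#' @return List with `times`, `freq` (Hz, `NA` at gaps), `gap` (logical),
#'   `pattern_id` (integer, `NA` at gaps).
#' @export
dominant_ridge <- function(patterns, band, times, grid_range = NULL) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(band, "band_spec"))
  if (!is.null(grid_range) &&
      (band$f_hi < grid_range[1L] || band$f_lo > grid_range[2L]))
    stop("band lies entirely outside the surface's frequency grid")
  freq <- rep(NA_real_, length(times))
  pid <- rep(NA_integer_, length(times))
  best <- rep(-Inf, length(times))
  for (p in patterns$patterns) {
    inband <- p$sc >= band$f_lo & p$sc <= band$f_hi & !p$edge
    if (!any(inband)) next
    ce <- sum(p$E[inband])
    ti <- match(round(p$t[inband], 9), round(times, 9))
    ok <- !is.na(ti)
    ti <- ti[ok]
    sel <- ce > best[ti] | (ce == best[ti] & (is.na(pid[ti]) | p$id < pid[ti]))
    ti <- ti[sel]
    freq[ti] <- p$sc[inband][ok][sel]
    pid[ti] <- p$id
    best[ti] <- ce
  }
  list(times = times, freq = freq, gap = is.na(freq), pattern_id = pid)
}
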