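# Shared fixtures, built in code at test time.

# A short clean synthetic ECG with constant-ish rate, cached per session.
fixture_ecg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(duration = 120, fs = 250, mean_rate = 1.0,
                          lf_amp = 0.03, hf_amp = 0.03,
                          rate_jitter_sd = 0.01, seed = 7)
      cache <<- c(simulate_record(cfg), list(config = cfg))
    }
    cache
  }
})

# --- byte-level WFDB / EDF fixture writers -------------------------------
# These construct files directly from the published byte layouts,
# independently of the package's readers, so read-back is a real check.

# pack two integer sample streams (same length) into WFDB format 212 bytes
pack_212 <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  u1 <- ifelse(s1 < 0, s1 + 4096L, s1)    # 12-bit two's complement
  u2 <- ifelse(s2 < 0, s2 + 4096L, s2)
  b1 <- bitwAnd(u1, 0xFFL)
  b2 <- bitwOr(bitwShiftR(u1, 8L), bitwShiftL(bitwShiftR(u2, 8L), 4L))
  b3 <- bitwAnd(u2, 0xFFL)
  as.raw(as.vector(rbind(b1, b2, b3)))
}

# write a 2-channel WFDB record (format 212) and return the header path
write_wfdb_fixture <- function(dir, name, adc1, adc2, fs = 250,
                               gain = 200, baseline = 0) {
  n <- length(adc1)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  writeLines(c(
    sprintf("%s 2 %g %d", name, fs, n),
    sprintf("%s 212 %g(%g)/mV 12 0 0 0 0 ch1", dat, gain, baseline),
    sprintf("%s 212 %g(%g)/mV 12 0 0 0 0 ch2", dat, gain, baseline)),
    hea)
  writeBin(pack_212(as.integer(adc1), as.integer(adc2)),
           file.path(dir, dat))
  hea
}

# write an MIT-format annotation file: words are (code<<10)|interval,
# little-endian; terminated by a zero word
write_atr_fixture <- function(path, sample_idx0, codes) {
  stopifnot(length(sample_idx0) == length(codes))
  iv <- diff(c(0L, as.integer(sample_idx0)))
  stopifnot(all(iv >= 0), all(iv < 1024))   # fixture stays in 10-bit range
  words <- bitwOr(bitwShiftL(as.integer(codes), 10L), iv)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(words, 0L)), con, size = 2L, endian = "little")
  path
}

# write a single-record EDF file with ns int16 channels
write_edf_fixture <- function(path, channels, fs, rec_dur, pmin, pmax,
                              dmin, dmax, labels = NULL) {
  ns <- length(channels)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  spr <- vapply(channels, length, integer(1))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(1, 8); wr(rec_dur, 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("transducer", 80)
  for (i in seq_len(ns)) wr("mV", 8)
  for (v in pmin) wr(v, 8)
  for (v in pmax) wr(v, 8)
  for (v in dmin) wr(v, 8)
  for (v in dmax) wr(v, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (v in spr) wr(v, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (ch in channels)
    writeBin(as.integer(ch), con, size = 2L, endian = "little")
  path
}
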