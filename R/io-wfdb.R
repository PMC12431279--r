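# Minimal WFDB reader: header (.hea) parsing plus signal formats 16 and
# 212, and MIT-format binary annotation files. Only the fields this
# package needs are interpreted; multi-segment records, other signal
# formats and EDF-compatible headers are out of scope.

.parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L) stop("malformed WFDB record line in ", hea_path)
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(strsplit(rec[3L], "/")[[1L]][1L])
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  if (nsig < 1L || length(lines) < 1L + nsig)
    stop("WFDB header lists ", nsig, " signals but has too few lines")
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- sub("x.*$", "", f[2L])            # strip samples-per-frame
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain_field <- sub("/.*$", "", gain_field)  # strip units
    baseline <- NA_real_
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
      gain_field <- sub("\\(.*$", "", gain_field)
    }
    gain <- as.numeric(gain_field)
    if (is.na(gain) || gain == 0) gain <- 200
    adczero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline,
         description = desc)
  })
  list(record = rec[1L], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

# decode format-212 bytes (raw vector) into an integer matrix [sample, signal]
.decode_212 <- function(bytes, nsig) {
  b <- as.integer(bytes)
  ntrip <- length(b) %/% 3L
  b <- b[seq_len(3L * ntrip)]
  b1 <- b[seq(1L, by = 3L, length.out = ntrip)]
  b2 <- b[seq(2L, by = 3L, length.out = ntrip)]
  b3 <- b[seq(3L, by = 3L, length.out = ntrip)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  tc <- function(v) ifelse(v > 2047L, v - 4096L, v)   # 12-bit two's complement
  flat <- as.vector(rbind(tc(s1), tc(s2)))
  nfr <- length(flat) %/% nsig
  matrix(flat[seq_len(nfr * nsig)], ncol = nsig, byrow = TRUE)
}

.read_record_wfdb <- function(path, channel, kind) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  hdr <- .parse_hea(hea)
  if (is.character(channel)) {
    descs <- vapply(hdr$signals, `[[`, character(1), "description")
    ci <- match(channel, descs)
    if (is.na(ci)) stop("unknown channel: ", channel)
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > hdr$nsig) stop("unknown channel index ", ci)
  }
  sig <- hdr$signals[[ci]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  sz <- file.info(dat)$size
  if (sig$format == "212") {
    bytes <- readBin(dat, "raw", n = sz)
    m <- .decode_212(bytes, hdr$nsig)
  } else if (sig$format == "16") {
    v <- readBin(dat, "integer", n = sz %/% 2L, size = 2L, signed = TRUE,
                 endian = "little")
    nfr <- length(v) %/% hdr$nsig
    m <- matrix(v[seq_len(nfr * hdr$nsig)], ncol = hdr$nsig, byrow = TRUE)
  } else {
    stop("unsupported WFDB signal format: ", sig$format)
  }
  if (!is.na(hdr$nsamp) && hdr$nsamp <= nrow(m)) m <- m[seq_len(hdr$nsamp), ,
                                                        drop = FALSE]
  x <- (m[, ci] - sig$baseline) / sig$gain
  signal_record(x, hdr$fs, kind = kind,
                label = if (nzchar(sig$description)) sig$description
                        else paste0("ch", ci))
}

# WFDB annotation type codes regarded as beats (normal and ectopic);
# rhythm changes, noise marks, comments etc. are dropped
.WFDB_BEAT_CODES <- c(1:13, 25L, 34L, 35L, 38L)

#' Read a binary MIT/WFDB annotation file
#'
#' Decodes the MIT annotation byte stream (2-byte little-endian words: 6-bit
#' type code, 10-bit time increment, with SKIP/NUM/SUB/CHN/AUX escape
#' codes) and returns the sample indices (1-based) of beat-class
#' annotations only.
#'
#' @param path Annotation file (e.g. `.atr`).
#' @return Integer vector of strictly increasing 1-based sample indices.
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  words <- readBin(path, "integer", n = sz %/% 2L, size = 2L, signed = FALSE,
                   endian = "little")
  t_cur <- 0L
  out <- integer(0)
  i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    interval <- bitwAnd(w, 0x3FFL)
    if (w == 0L) break                         # EOF
    if (code == 59L) {                         # SKIP: 4-byte interval follows
      if (i + 2L > length(words)) break
      hi <- words[i + 1L]; lo <- words[i + 2L]
      t_cur <- t_cur + hi * 65536L + lo
      i <- i + 3L
      next
    } else if (code == 63L) {                  # AUX: interval = byte count
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
      next
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    t_cur <- t_cur + interval
    if (code %in% .WFDB_BEAT_CODES) out <- c(out, t_cur)
    i <- i + 1L
  }
  out + 1L    # WFDB times are 0-based sample numbers
}

.read_record_edf <- function(path, channel, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  rd(8L)                      # version
  rd(80L); rd(80L)            # patient, recording id
  rd(8L); rd(8L)              # start date, time
  rd(8L)                      # header byte count
  rd(44L)                     # reserved
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)                       # transducer
  for (i in seq_len(ns)) rd(8L)                        # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(ns)) rd(80L)                       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(ns)) rd(32L)                       # reserved
  if (is.character(channel)) {
    ci <- match(channel, labels)
    if (is.na(ci)) stop("unknown channel: ", channel)
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > ns) stop("unknown channel index ", ci)
  }
  per_rec <- sum(spr)
  digital <- integer(0)
  samples <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = per_rec, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < per_rec) break
    off <- if (ci > 1L) sum(spr[seq_len(ci - 1L)]) else 0L
    samples[[r]] <- block[off + seq_len(spr[ci])]
  }
  digital <- unlist(samples)
  scale <- (pmax[ci] - pmin[ci]) / (dmax[ci] - dmin[ci])
  x <- pmin[ci] + (digital - dmin[ci]) * scale
  fs <- spr[ci] / rec_dur
  signal_record(x, fs, kind = kind, label = labels[ci])
}
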