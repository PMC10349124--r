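# Minimal European Data Format (EDF) support: ASCII header + 16-bit
# little-endian samples. Covers the subset needed for continuous EEG
# recordings (one data record holding the whole signal, identical rate for
# all channels). Field layout follows the EDF specification of Kemp et al.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path, phys_range = NULL) {
  ns <- nrow(rec$data)
  if (ns < 1L) stop("EDF requires at least one channel")
  n_samp <- ncol(rec$data)
  labels <- rec$channel_labels
  too_long <- nchar(labels) > 16L
  if (any(too_long)) {
    earbci_log("EDF labels truncated to 16 characters: ",
               paste(labels[too_long], collapse = ", "))
    warning("EDF channel labels longer than 16 characters were truncated: ",
            paste(labels[too_long], collapse = ", "))
  }
  # physical scaling per channel; digital range is the full int16 span
  dig_min <- -32768; dig_max <- 32767
  if (is.null(phys_range)) {
    pmin <- apply(rec$data, 1, min)
    pmax <- apply(rec$data, 1, max)
    flat <- pmax - pmin < .Machine$double.eps
    pmin[flat] <- pmin[flat] - 1
    pmax[flat] <- pmax[flat] + 1
  } else {
    stopifnot(length(phys_range) == 2L, phys_range[1] < phys_range[2])
    pmin <- rep(phys_range[1], ns)
    pmax <- rep(phys_range[2], ns)
  }
  dur <- n_samp / rec$rate

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  # 256-byte static header
  wr(edf_pad("0", 8))                       # version
  wr(edf_pad("X X X X", 80))                # patient id (anonymous)
  wr(edf_pad("Startdate X earbci", 80))     # recording id
  wr(edf_pad("01.01.00", 8))                # start date
  wr(edf_pad("00.00.00", 8))                # start time
  wr(edf_pad(256 + ns * 256, 8))            # header bytes
  wr(edf_pad("", 44))                       # reserved
  wr(edf_pad(1, 8))                         # number of data records
  wr(edf_num(dur, 8))                       # record duration, seconds
  wr(edf_pad(ns, 4))                        # number of signals
  # per-signal header blocks (each field written for all signals in turn)
  for (lab in labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))          # transducer
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))         # physical dimension
  for (i in seq_len(ns)) wr(edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wr(edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))          # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(n_samp, 8))       # samples per record
  for (i in seq_len(ns)) wr(edf_pad("", 32))          # reserved
  # one data record: each signal's samples in sequence, int16 LE
  for (i in seq_len(ns)) {
    gain <- (pmax[i] - pmin[i]) / (dig_max - dig_min)
    dig <- round((rec$data[i, ] - pmin[i]) / gain + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) suppressWarnings(as.numeric(trimws(rd(n))))
  ver <- trimws(rd(8))
  if (!identical(ver, "0")) stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)              # ids, date, time
  num(8)                                    # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("EDF header of ", path, " lacks a usable rate or signal count")
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)              # physical dimension
  pmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal rates are not supported: ", path)
  }
  rate <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- (dig - dmin[i]) * gain + pmin[i]
    }
  }
  recording(data, rate = rate, channel_labels = labels)
}
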