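# Minimal reader/writer for 16-bit European Data Format (EDF) files.
# Continuous recordings only, one common sampling rate across signals,
# 1-s data records.  Sufficient for polysomnography signal exchange; no
# EDF+ annotations.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF (16-bit)
#'
#' Physical range per channel is the observed signal range (so quantization
#' error is at most range/65535); digital range is -32768..32767; data
#' records last 1 s, the tail record is zero-padded.
#'
#' @param rec a [psg_recording()] (or numeric matrix with `fs` given).
#' @param path output file.
#' @param fs sampling rate, required when `rec` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, fs = NULL) {
  if (inherits(rec, "psg_recording")) {
    sig <- rec$signal; fs <- rec$fs; labels <- rec$channel_labels
  } else {
    sig <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1L)
    if (is.null(fs)) stop("fs required when writing a bare matrix")
    labels <- paste0("ch", seq_len(nrow(sig)))
  }
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(sig)
  spr <- as.integer(fs)                       # samples per 1-s record
  n_rec <- ceiling(ncol(sig) / spr)
  pmin_ <- apply(sig, 1L, min)
  pmax_ <- apply(sig, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1              # avoid zero physical range
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4),
    paste(pad_field(labels, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(pad_field(sprintf("%.8g", pmin_), 8), collapse = ""),
    paste(pad_field(sprintf("%.8g", pmax_), 8), collapse = ""),
    paste(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste(rep(pad_field("32767", 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the physical limits exactly as a reader will parse them, so the
  # digital->physical mapping round-trips
  pmin_r <- as.numeric(sprintf("%.8g", pmin_))
  pmax_r <- as.numeric(sprintf("%.8g", pmax_))
  gain <- (pmax_r - pmin_r) / 65535
  padded <- matrix(0, ns, n_rec * spr)
  padded[, seq_len(ncol(sig))] <- sig
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((padded[ch, cols] - pmin_r[ch]) / gain[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF file.
#' @return list with `signal` (channels x samples matrix, physical units),
#'   `fs` (Hz) and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                    # version
  rd(80); rd(80); rd(8); rd(8)             # ids, date, time
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF: zero signals")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) stop("EDF reader requires one sampling rate")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     signed = TRUE, endian = "little")
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      sig[ch, cols] <- (dig - dmin_[ch]) * gain[ch] + pmin_[ch]
    }
  }
  list(signal = sig, fs = fs, labels = labels)
}
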