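# Data model for polysomnography recordings: signal + hypnogram + artifact
# mask, stage/artifact sample masks, and time-domain normalization.

SLEEP_STAGES <- c("Wake", "N1", "N2", "N3", "REM", "Unknown")
EPOCH_SEC <- 30
ARTIFACT_BIN_SEC <- 5

# external one-token-per-epoch dialect <-> internal stage names
.stage_token_map <- c(W = "Wake", N1 = "N1", N2 = "N2", N3 = "N3", R = "REM",
                      U = "Unknown")

#' Polysomnography recording container
#'
#' Bundles a multi-channel signal (microvolts), its sampling rate, channel
#' labels (10-20 system), a hypnogram of 30-s sleep stages and an artifact
#' mask of 5-s bins per channel (`TRUE` = rejected).
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz; must exceed 60 Hz (twice the highest
#'   analyzed frequency of 30 Hz).
#' @param channel_labels character vector, one label per channel.
#' @param hypnogram optional [hypnogram()]; defaults to all-Unknown epochs
#'   covering the recording.
#' @param artifact_mask optional logical matrix channels x 5-s bins;
#'   defaults to no rejections.
#' @return object of class `psg_recording`.
#' @export
psg_recording <- function(signal, fs, channel_labels = NULL,
                          hypnogram = NULL, artifact_mask = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("signal must be a numeric matrix (channels x samples)")
  }
  if (nrow(signal) == 0L) stop("recording has zero channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (fs <= 2 * 30) stop("fs must exceed 60 Hz (2 x highest analyzed frequency)")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length must match channel count")
  }
  dur <- ncol(signal) / fs
  n_epochs <- ceiling(dur / EPOCH_SEC)
  if (is.null(hypnogram)) {
    hypnogram <- new_hypnogram(rep("Unknown", n_epochs))
  } else {
    hypnogram <- as_hypnogram(hypnogram)
    if (abs(length(hypnogram) * EPOCH_SEC - dur) > EPOCH_SEC) {
      stop("hypnogram covers ", length(hypnogram) * EPOCH_SEC,
           " s but the signal lasts ", round(dur, 2), " s")
    }
  }
  n_bins <- ceiling(dur / ARTIFACT_BIN_SEC)
  if (is.null(artifact_mask)) {
    artifact_mask <- matrix(FALSE, nrow(signal), n_bins)
  } else {
    if (is.vector(artifact_mask)) {
      artifact_mask <- matrix(artifact_mask, nrow = nrow(signal),
                              ncol = length(artifact_mask), byrow = TRUE)
    }
    if (ncol(artifact_mask) != n_bins || nrow(artifact_mask) != nrow(signal)) {
      stop("artifact_mask must be channels x ceiling(duration/5s) bins")
    }
    storage.mode(artifact_mask) <- "logical"
  }
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         hypnogram = hypnogram, artifact_mask = artifact_mask),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("psg_recording: %d channel(s) x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs / 60))
  st <- table(factor(unclass(x$hypnogram), levels = SLEEP_STAGES))
  cat("  stages (30-s epochs):",
      paste(sprintf("%s=%d", names(st)[st > 0], st[st > 0]), collapse = " "), "\n")
  cat(sprintf("  artifact bins rejected: %d/%d\n",
              sum(x$artifact_mask), length(x$artifact_mask)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)
duration_sec <- function(rec) ncol(rec$signal) / rec$fs

new_hypnogram <- function(stages) {
  stopifnot(all(stages %in% SLEEP_STAGES))
  structure(stages, class = "hypnogram")
}

as_hypnogram <- function(x) {
  if (inherits(x, "hypnogram")) return(x)
  x <- as.character(x)
  bad <- !(x %in% SLEEP_STAGES)
  if (any(bad)) {
    # accept the external token dialect too
    mapped <- .stage_token_map[x[bad]]
    x[bad] <- ifelse(is.na(mapped), x[bad], mapped)
    bad <- !(x %in% SLEEP_STAGES)
    if (any(bad)) {
      warning("unknown stage token(s) ", paste(unique(x[bad]), collapse = ", "),
              " mapped to Unknown")
      x[bad] <- "Unknown"
    }
  }
  new_hypnogram(x)
}

#' Read a hypnogram from plain text
#'
#' One stage token per 30-s epoch from `{W, N1, N2, N3, R}`, separated by
#' commas or newlines.  Unknown tokens map to `Unknown` with a warning.
#'
#' @param path text file path.
#' @return a `hypnogram` (character vector of internal stage names).
#' @export
load_hypnogram <- function(path) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(raw, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty hypnogram file: ", path)
  as_hypnogram(tokens)
}

#' @rdname load_hypnogram
#' @param hyp hypnogram to write.
#' @export
write_hypnogram <- function(hyp, path) {
  inv <- c(Wake = "W", N1 = "N1", N2 = "N2", N3 = "N3", REM = "R",
           Unknown = "U")
  writeLines(inv[unclass(as_hypnogram(hyp))], path)
  invisible(path)
}

#' Read / write an artifact mask
#'
#' Text format: one row per channel, one 0/1 per 5-s bin (1 = rejected),
#' whitespace-separated.
#' @param path file path.
#' @return logical matrix channels x bins.
#' @export
load_artifact_mask <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  m != 0
}

#' @rdname load_artifact_mask
#' @param mask logical matrix to write.
#' @export
write_artifact_mask <- function(mask, path) {
  utils::write.table(mask * 1L, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a polysomnography recording
#'
#' Reads the signal from EDF (16-bit) or from a plain numeric matrix file
#' (channels in columns, tab/space separated, with a `# fs=<Hz>` and optional
#' `# labels=<a,b,...>` header line).  Companion hypnogram / artifact-mask
#' files may be supplied; absent ones are initialized to all-Unknown /
#' no-rejections.
#'
#' @param path signal file.
#' @param format `"edf"` or `"matrix"`; guessed from the extension by default.
#' @param hypnogram_path,artifact_path optional companion files.
#' @return a [psg_recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "matrix"),
                           hypnogram_path = NULL, artifact_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    e <- read_edf(path)
    sig <- e$signal; fs <- e$fs; labels <- e$labels
  } else {
    header <- readLines(path, n = 5L)
    fs_line <- grep("^#\\s*fs\\s*=", header, value = TRUE)
    if (length(fs_line) == 0L) stop("matrix file lacks a '# fs=<Hz>' header")
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1]))
    lab_line <- grep("^#\\s*labels\\s*=", header, value = TRUE)
    m <- as.matrix(utils::read.table(path, comment.char = "#"))
    if (ncol(m) == 0L || nrow(m) == 0L) stop("matrix file contains no channels")
    sig <- t(m)
    dimnames(sig) <- NULL
    labels <- if (length(lab_line)) {
      strsplit(sub("^#\\s*labels\\s*=\\s*", "", lab_line[1]), ",")[[1]]
    } else NULL
  }
  hyp <- if (!is.null(hypnogram_path)) load_hypnogram(hypnogram_path) else NULL
  art <- if (!is.null(artifact_path)) load_artifact_mask(artifact_path) else NULL
  psg_recording(sig, fs, labels, hyp, art)
}

#' Write a recording's signal as a plain numeric matrix file
#'
#' @param rec a [psg_recording()].
#' @param path output file.
#' @export
write_recording_matrix <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec$fs), con)
  writeLines(paste0("# labels=", paste(rec$channel_labels, collapse = ",")), con)
  utils::write.table(t(rec$signal), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-sample stage selection mask
#'
#' `TRUE` for samples whose 30-s epoch stage is in `stages` and (if
#' `exclude_artifacts`) whose 5-s bin is not rejected on `channel`.
#'
#' @param rec a [psg_recording()].
#' @param stages character vector of stage names (internal or token dialect).
#' @param exclude_artifacts drop samples in rejected 5-s bins.
#' @param channel channel index or label whose artifact row is used.
#' @return logical vector, one entry per sample.
#' @export
stage_sample_mask <- function(rec, stages, exclude_artifacts = TRUE,
                              channel = 1L) {
  if (length(stages) == 0L) stop("empty stage set")
  stages <- unclass(as_hypnogram(stages))
  ch <- resolve_channel(rec, channel)
  n <- n_samples(rec)
  epoch_of <- pmin(((seq_len(n) - 1L) %/% (EPOCH_SEC * rec$fs)) + 1L,
                   length(rec$hypnogram))
  mask <- unclass(rec$hypnogram)[epoch_of] %in% stages
  if (exclude_artifacts) {
    bin_of <- ((seq_len(n) - 1L) %/% (ARTIFACT_BIN_SEC * rec$fs)) + 1L
    mask <- mask & !rec$artifact_mask[ch, bin_of]
  }
  mask
}

resolve_channel <- function(rec, channel) {
  if (is.character(channel)) {
    ch <- match(channel, rec$channel_labels)
    if (is.na(ch)) stop("unknown channel label: ", channel)
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > nrow(rec$signal)) stop("channel index out of range")
    ch
  }
}

#' Z-normalize a recording in the time domain
#'
#' Per channel, subtracts the mean and divides by the population standard
#' deviation (divisor n) computed over the masked samples, and applies the
#' transform to the whole channel trace, so that event epochs extracted
#' anywhere are on the same scale.
#'
#' @param rec a [psg_recording()].
#' @param mask logical sample mask (e.g. artifact-free NREM); a matrix with
#'   one row per channel gives each channel its own estimation support.
#' @return normalized `psg_recording`.
#' @export
znormalize <- function(rec, mask = NULL) {
  n <- n_samples(rec)
  if (is.null(mask)) mask <- rep(TRUE, n)
  mm <- if (is.matrix(mask)) mask else
    matrix(mask, nrow = nrow(rec$signal), ncol = n, byrow = TRUE)
  for (ch in seq_len(nrow(rec$signal))) {
    sel <- rec$signal[ch, mm[ch, ]]
    if (length(sel) < 2L) stop("mask selects < 2 samples on channel ",
                               rec$channel_labels[ch])
    mu <- mean(sel)
    sd_pop <- sqrt(mean((sel - mu)^2))
    if (sd_pop == 0) stop("zero variance on channel ", rec$channel_labels[ch])
    rec$signal[ch, ] <- (rec$signal[ch, ] - mu) / sd_pop
  }
  rec
}
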