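# Individualized slow-oscillation and spindle event detection, epoch
# extraction, density and co-occurrence.

#' Detect slow-oscillation events
#'
#' Zero-phase band filtering (high-pass 0.16 Hz, then low-pass 2 Hz);
#' candidates are the intervals between consecutive positive-to-negative
#' zero crossings (one down-state then one up-state); candidates lasting
#' 0.8-2 s are kept and those whose trough-to-peak amplitude exceeds the
#' 75th percentile of all duration-valid candidate amplitudes become
#' events.  Candidates must lie entirely inside the mask, so events never
#' overlap rejected 5-s bins.
#'
#' @param rec a [psg_recording()] (typically z-normalized; the percentile
#'   rule is scale-free either way).
#' @param channel channel index or label.
#' @param mask logical sample mask (stage + artifacts), e.g. from
#'   [stage_sample_mask()].
#' @param dur_range duration criterion in seconds.
#' @param percentile amplitude percentile threshold (events must exceed it
#'   strictly).
#' @return data.frame of events: `start`, `trough_time`, `peak_time`, `end`
#'   (s), `duration` (s), `amplitude` (filtered trough-to-peak), `channel`.
#' @export
detect_so <- function(rec, channel = 1L, mask = NULL,
                      dur_range = c(0.8, 2), percentile = 75) {
  ch <- resolve_channel(rec, channel)
  fs <- rec$fs
  n <- n_samples(rec)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (sum(mask) < 60 * fs) stop("mask must select at least 60 s of data")
  x <- rec$signal[ch, ]
  filt <- lowpass_filter(highpass_filter(x, fs, 0.16, trans_width = 0.1),
                         fs, 2, trans_width = 0.5)
  pos <- filt > 0
  cross <- which(pos[-n] & !pos[-1])      # positive-to-negative crossings
  empty <- data.frame(start = numeric(0), trough_time = numeric(0),
                      peak_time = numeric(0), end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      channel = character(0))
  if (length(cross) < 2L) return(empty)
  # sub-sample crossing positions by linear interpolation (duration criterion)
  frac <- filt[cross] / (filt[cross] - filt[cross + 1L])
  t_cross <- (cross - 1 + frac) / fs
  cand <- data.frame(start = t_cross[-length(t_cross)], end = t_cross[-1])
  cand$duration <- cand$end - cand$start
  cand <- cand[cand$duration >= dur_range[1] & cand$duration <= dur_range[2], ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  i0 <- floor(cand$start * fs) + 1L
  i1 <- ceiling(cand$end * fs) + 1L
  i1 <- pmin(i1, n)
  keep <- logical(nrow(cand))
  trough <- peak <- integer(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    idx <- i0[k]:i1[k]
    if (!all(mask[idx])) next
    tr <- idx[which.min(filt[idx])]
    after <- tr:i1[k]
    pk <- after[which.max(filt[after])]
    if (pk <= tr) next
    keep[k] <- TRUE; trough[k] <- tr; peak[k] <- pk
  }
  cand <- cand[keep, , drop = FALSE]
  trough <- trough[keep]; peak <- peak[keep]
  if (nrow(cand) == 0L) return(empty)
  amp <- filt[peak] - filt[trough]
  thr <- stats::quantile(amp, percentile / 100, names = FALSE)
  sel <- amp > thr
  out <- data.frame(start = cand$start[sel],
                    trough_time = (trough[sel] - 1) / fs,
                    peak_time = (peak[sel] - 1) / fs,
                    end = cand$end[sel],
                    duration = cand$duration[sel],
                    amplitude = amp[sel],
                    channel = rec$channel_labels[ch])
  rownames(out) <- NULL
  out
}

#' Detect sleep-spindle events
#'
#' Zero-phase bandpass of +-2 Hz around the individual spindle peak
#' frequency; the instantaneous amplitude (Hilbert envelope) is smoothed
#' with a 200-ms centered moving average; events are runs where the
#' smoothed envelope strictly exceeds its 75th percentile (computed over
#' masked samples) lasting 0.5-3 s.  The event anchor is the envelope
#' maximum within the run.
#'
#' @inheritParams detect_so
#' @param peak_freq individual spindle peak frequency in Hz (10-18).
#' @param smooth_sec moving-average width in seconds.
#' @return data.frame of events: `start`, `peak_time`, `end`, `duration`,
#'   `peak_amplitude` (envelope units), `center_freq`, `channel`.
#' @export
detect_spindles <- function(rec, channel = 1L, mask = NULL, peak_freq,
                            dur_range = c(0.5, 3), percentile = 75,
                            smooth_sec = 0.2) {
  if (peak_freq < 10 || peak_freq > 18) stop("peak_freq must lie in [10, 18] Hz")
  ch <- resolve_channel(rec, channel)
  fs <- rec$fs
  n <- n_samples(rec)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (sum(mask) < 60 * fs) stop("mask must select at least 60 s of data")
  x <- rec$signal[ch, ]
  filt <- bandpass_filter(x, fs, peak_freq - 2, peak_freq + 2)
  env <- moving_average(Mod(analytic_signal(filt)), round(smooth_sec * fs))
  thr <- stats::quantile(env[mask], percentile / 100, names = FALSE)
  above <- env > thr & mask
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- r$lengths / fs
  sel <- which(r$values & dur >= dur_range[1] & dur <= dur_range[2])
  if (length(sel) == 0L) {
    return(data.frame(start = numeric(0), peak_time = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      peak_amplitude = numeric(0), center_freq = numeric(0),
                      channel = character(0)))
  }
  peak_idx <- vapply(sel, function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(env[idx])]
  }, 0L)
  out <- data.frame(start = (starts[sel] - 1) / fs,
                    peak_time = (peak_idx - 1) / fs,
                    end = (ends[sel] - 1) / fs,
                    duration = dur[sel],
                    peak_amplitude = env[peak_idx],
                    center_freq = peak_freq,
                    channel = rec$channel_labels[ch])
  rownames(out) <- NULL
  out
}

#' Extract event-locked epochs
#'
#' Cuts +-2.5-s epochs around event anchors (SO troughs or spindle peaks)
#' from the channel trace.  Anchors closer than 2.5 s to either recording
#' edge are dropped with a warning.  With `normalize = TRUE` each epoch is
#' independently z-scored (population SD), the per-event normalization used
#' before coupling estimation.
#'
#' @param rec a [psg_recording()].
#' @param anchors anchor times in seconds (e.g. `events$trough_time` or
#'   `events$peak_time`).
#' @param channel channel index or label.
#' @param half_width half epoch length in seconds.
#' @param normalize z-score each epoch.
#' @return object of class `event_epochs`: list with `data`
#'   (events x samples matrix; the anchor is the center sample), `fs`,
#'   `anchors` (surviving anchor times), `normalized`.
#' @export
extract_epochs <- function(rec, anchors, channel = 1L, half_width = 2.5,
                           normalize = TRUE) {
  ch <- resolve_channel(rec, channel)
  fs <- rec$fs
  n <- n_samples(rec)
  hw <- round(half_width * fs)
  ctr <- round(anchors * fs) + 1L
  ok <- ctr - hw >= 1L & ctr + hw <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) within ", half_width,
            " s of the recording edge dropped")
  }
  ctr <- ctr[ok]
  m <- matrix(NA_real_, length(ctr), 2L * hw + 1L)
  x <- rec$signal[ch, ]
  for (i in seq_along(ctr)) {
    ep <- x[(ctr[i] - hw):(ctr[i] + hw)]
    if (normalize) {
      s <- sqrt(mean((ep - mean(ep))^2))
      if (s == 0) stop("zero-variance epoch at anchor ", anchors[ok][i], " s")
      ep <- (ep - mean(ep)) / s
    }
    m[i, ] <- ep
  }
  structure(list(data = m, fs = fs, anchors = anchors[ok],
                 normalized = normalize, channel = rec$channel_labels[ch]),
            class = "event_epochs")
}

#' Spindle density per 30-s stage epoch
#'
#' Number of events whose anchor lies in epochs of the requested stage,
#' divided by the number of such epochs.
#'
#' @param anchors event anchor times in seconds.
#' @param hypnogram a hypnogram (internal names or token dialect).
#' @param stage stage name, default `"N3"`.
#' @return events per 30-s epoch.
#' @export
spindle_density <- function(anchors, hypnogram, stage = "N3") {
  hyp <- unclass(as_hypnogram(hypnogram))
  n_ep <- sum(hyp == stage)
  if (n_ep == 0L) stop("hypnogram holds no ", stage, " epochs")
  ep_of <- floor(anchors / EPOCH_SEC) + 1L
  sum(hyp[pmin(ep_of, length(hyp))] == stage) / n_ep
}

#' SO-spindle co-occurrence rate
#'
#' Percentage of spindle events whose peak lies within a +-`window` interval
#' (boundary inclusive) of any SO trough.  The alternative normalization
#' (percentage of SO events with a spindle peak nearby) is available via
#' `denominator = "so"`.
#'
#' @param so data.frame from [detect_so()].
#' @param spindles data.frame from [detect_spindles()].
#' @param window half window in seconds.
#' @param denominator `"spindle"` (default) or `"so"`.
#' @return percentage in \[0, 100\]; `NA` when the denominator set is empty.
#' @export
cooccurrence_rate <- function(so, spindles, window = 2.5,
                              denominator = c("spindle", "so")) {
  denominator <- match.arg(denominator)
  if (denominator == "spindle") {
    if (nrow(spindles) == 0L) return(NA_real_)
    if (nrow(so) == 0L) return(0)
    hit <- vapply(spindles$peak_time, function(t) {
      any(abs(so$trough_time - t) <= window + 1e-12)
    }, TRUE)
  } else {
    if (nrow(so) == 0L) return(NA_real_)
    if (nrow(spindles) == 0L) return(0)
    hit <- vapply(so$trough_time, function(t) {
      any(abs(spindles$peak_time - t) <= window + 1e-12)
    }, TRUE)
  }
  100 * mean(hit)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching of detected anchors to reference anchors
#' within a tolerance; returns precision (matched detections / detections)
#' and recall (matched references / references).  For the slow-oscillation
#' detector -- by construction a top-quartile-amplitude detector -- recall
#' should be scored against the reference events in the top quartile of
#' injected amplitude (pass that subset as `reference`).
#'
#' @param detected detected anchor times (s).
#' @param reference ground-truth anchor times (s) for recall.
#' @param tol matching tolerance (s).
#' @param precision_reference optional larger truth set for precision
#'   (defaults to `reference`).
#' @return list with `precision`, `recall`, `n_detected`, `n_reference`.
#' @export
score_detections <- function(detected, reference, tol,
                             precision_reference = reference) {
  match_count <- function(det, ref) {
    used <- logical(length(ref))
    hits <- 0L
    for (t in det) {
      d <- abs(ref - t)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tol) {
        used[j] <- TRUE
        hits <- hits + 1L
      }
    }
    hits
  }
  prec <- if (length(detected) == 0L) NA_real_ else
    match_count(detected, precision_reference) / length(detected)
  rec <- if (length(reference) == 0L) NA_real_ else
    match_count(detected, reference) / length(reference)
  list(precision = prec, recall = rec,
       n_detected = length(detected), n_reference = length(reference))
}
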