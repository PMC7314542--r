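# Spectral parameterization: Hann-windowed sliding spectra, IRASA separation
# of the 1/f fractal component from oscillatory residuals, band-peak
# extraction, and the full-night multitaper spectrogram.

SPECTRAL_WIN_SEC <- 15
SPECTRAL_STEP_SEC <- 1
IRASA_HSET <- seq(1.1, 1.9, by = 0.05)

# contiguous TRUE runs of a sample mask long enough to hold one window
mask_runs <- function(mask, min_len) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

spectral_freq_grid <- function() (2:450) / SPECTRAL_WIN_SEC  # 0.133-30 Hz

new_spectral_decomp <- function(freqs, mixed, fractal = NULL, residual = NULL,
                                channels) {
  structure(list(freqs = freqs, mixed = mixed, fractal = fractal,
                 residual = residual, channels = channels),
            class = "spectral_decomp")
}

#' @export
print.spectral_decomp <- function(x, ...) {
  cat(sprintf("spectral_decomp: %d channel(s), %.2f-%.0f Hz (%d bins)%s\n",
              nrow(x$mixed), min(x$freqs), max(x$freqs), length(x$freqs),
              if (is.null(x$fractal)) ", mixed only" else ", IRASA-decomposed"))
  invisible(x)
}

# shared window bookkeeping; returns list(runs, L, step, starts per run)
spectral_plan <- function(rec, mask, max_sec = Inf) {
  fs <- rec$fs
  L <- round(SPECTRAL_WIN_SEC * fs)
  step <- round(SPECTRAL_STEP_SEC * fs)
  runs <- mask_runs(mask, L)
  if (nrow(runs) == 0L) {
    stop("mask holds no full ", SPECTRAL_WIN_SEC, "-s window")
  }
  max_win <- if (is.finite(max_sec)) {
    max(1L, floor((max_sec - SPECTRAL_WIN_SEC) / SPECTRAL_STEP_SEC) + 1L)
  } else Inf
  plan <- list(); total <- 0L
  for (i in seq_len(nrow(runs))) {
    if (total >= max_win) break
    starts <- seq(runs$start[i], runs$end[i] - L + 1L, by = step)
    if (total + length(starts) > max_win) {
      starts <- starts[seq_len(max_win - total)]
    }
    total <- total + length(starts)
    plan[[i]] <- list(run = c(runs$start[i], runs$end[i]), starts = starts)
  }
  list(plan = plan, L = L, step = step, n_win = total, fs = fs)
}

#' Mixed (fractal + oscillatory) power spectrum
#'
#' Hann-tapered FFT power on 15-s windows slid in 1-s steps, windows fully
#' inside the supplied stage/artifact mask; power is averaged across windows
#' and then log10-transformed.  Frequency grid: 0.13-30 Hz at the native
#' 1/15 Hz resolution.
#'
#' @param rec a [psg_recording()] (typically z-normalized).
#' @param mask logical sample mask (see [stage_sample_mask()]).
#' @param channels channel indices/labels; default all.
#' @param max_sec cap on analyzed window span per channel (speed knob).
#' @return a `spectral_decomp` with the `mixed` slot filled.
#' @export
mixed_spectrum <- function(rec, mask, channels = NULL, max_sec = Inf) {
  sp <- spectral_plan(rec, mask, max_sec)
  chs <- if (is.null(channels)) seq_len(nrow(rec$signal)) else
    vapply(channels, resolve_channel, 0L, rec = rec)
  ft <- spectral_freq_grid()
  out <- matrix(NA_real_, length(chs), length(ft))
  for (j in seq_along(chs)) {
    acc <- numeric(length(ft))
    x <- rec$signal[chs[j], ]
    for (pl in sp$plan) {
      # periodogram bins are k/15 Hz; keep k = 2..450
      acc <- acc + hann_periodogram_sum(x, pl$starts, sp$L, sp$fs, 450L)[2:450]
    }
    out[j, ] <- log10(acc / sp$n_win)
  }
  new_spectral_decomp(ft, out, channels = rec$channel_labels[chs])
}

#' IRASA fractal/oscillatory decomposition
#'
#' Irregular-resampling auto-spectral analysis: each masked segment is
#' resampled by factors `h` of 1.1-1.9 (step 0.05) and by the reciprocal
#' `1/h`.  Read at the nominal rate, resampling shifts oscillatory peaks
#' (to f/h and f*h) but leaves a power law `f^-beta` invariant in the
#' geometric mean of each (h, 1/h) pair; the median across factors then
#' averages out the shifted oscillatory peaks, leaving the fractal
#' component.  Windowed power is averaged across windows per factor before
#' the geometric mean and median (averaging first keeps the chi-squared
#' periodogram noise from biasing the geometric mean downward).  The
#' oscillatory residual is `mixed - fractal` in log10 space.
#'
#' @inheritParams mixed_spectrum
#' @param hset resampling factors.
#' @return a `spectral_decomp` with `mixed`, `fractal` and `residual` filled.
#' @export
irasa <- function(rec, mask, channels = NULL, hset = IRASA_HSET,
                  max_sec = Inf) {
  sp <- spectral_plan(rec, mask, max_sec)
  chs <- if (is.null(channels)) seq_len(nrow(rec$signal)) else
    vapply(channels, resolve_channel, 0L, rec = rec)
  ft <- spectral_freq_grid()
  fs <- sp$fs; L <- sp$L
  mixed <- matrix(NA_real_, length(chs), length(ft))
  fractal <- matrix(NA_real_, length(chs), length(ft))
  for (j in seq_along(chs)) {
    x <- rec$signal[chs[j], ]
    mix_acc <- numeric(length(ft))
    frac_sums <- vector("list", length(hset))
    for (hi in seq_along(hset)) {
      h <- hset[hi]
      # FFT-friendly window lengths; the periodogram grid uses the actual
      # length, so small deviations from round(L*h) are exact, not approximate
      Lu <- five_smooth_near(round(L * h)); Ld <- five_smooth_near(round(L / h))
      ku <- min((Lu - 1) %/% 2, ceiling(30.5 * Lu / fs))
      kd <- min((Ld - 1) %/% 2, ceiling(30.5 * Ld / fs))
      frac_sums[[hi]] <- list(up = numeric(ku), dw = numeric(kd),
                              Lu = Lu, Ld = Ld, ku = ku, kd = kd)
    }
    for (pl in sp$plan) {
      rel <- pl$starts - pl$run[1] + 1L
      span <- max(rel) + L - 1L             # windows only need this span
      run <- x[pl$run[1]:(pl$run[1] + span - 1L)]
      mix_acc <- mix_acc + hann_periodogram_sum(run, rel, L, fs, 450L)[2:450]
      for (hi in seq_along(hset)) {
        h <- hset[hi]
        fsums <- frac_sums[[hi]]
        m_up <- five_smooth_near(round(span * h))
        m_dw <- five_smooth_near(round(span / h))
        h_up <- m_up / span; h_dw <- m_dw / span
        run_up <- resample_fft(run, m_up)
        run_dw <- resample_fft(run, m_dw)
        s_up <- pmax(1L, pmin(round((rel - 1) * h_up) + 1L, m_up - fsums$Lu + 1L))
        s_dw <- pmax(1L, pmin(round((rel - 1) * h_dw) + 1L, m_dw - fsums$Ld + 1L))
        fsums$up <- fsums$up +
          hann_periodogram_sum(run_up, s_up, fsums$Lu, fs, fsums$ku)
        fsums$dw <- fsums$dw +
          hann_periodogram_sum(run_dw, s_dw, fsums$Ld, fs, fsums$kd)
        frac_sums[[hi]] <- fsums
      }
    }
    gm <- matrix(NA_real_, length(hset), length(ft))
    for (hi in seq_along(hset)) {
      fsums <- frac_sums[[hi]]
      fu <- (seq_along(fsums$up)) * fs / fsums$Lu
      fd <- (seq_along(fsums$dw)) * fs / fsums$Ld
      pu <- stats::approx(fu, fsums$up / sp$n_win, xout = ft, rule = 2)$y
      pd <- stats::approx(fd, fsums$dw / sp$n_win, xout = ft, rule = 2)$y
      gm[hi, ] <- sqrt(pu * pd)
    }
    mixed[j, ] <- log10(mix_acc / sp$n_win)
    fractal[j, ] <- log10(apply(gm, 2, stats::median))
  }
  new_spectral_decomp(ft, mixed, fractal, mixed - fractal,
                      channels = rec$channel_labels[chs])
}

#' Oscillatory band peak from the 1/f-corrected residual
#'
#' Finds local maxima of the oscillatory residual (sign change of the first
#' difference) inside a frequency band and returns the one with the largest
#' 1/f-corrected amplitude; ties go to the lower frequency.  Returns `NULL`
#' when the band holds no local maximum with positive residual.
#'
#' @param dec a `spectral_decomp` from [irasa()].
#' @param band `"so"` (< 2 Hz), `"spindle"` (10-18 Hz), `"theta"`
#'   (4-8 Hz; the conventional band, configurable) or a numeric
#'   `c(lo, hi)` in Hz.
#' @param channel channel index or label within `dec$channels`.
#' @return list with `freq`, `amp` (residual log-power), `band`, `channel`,
#'   or `NULL`.
#' @export
find_band_peak <- function(dec, band = "spindle", channel = 1L) {
  if (is.null(dec$residual)) stop("decomposition has no residual; run irasa()")
  if (is.character(channel)) channel <- match(channel, dec$channels)
  band_name <- if (is.character(band)) band else "custom"
  lim <- if (is.character(band)) {
    switch(band,
           so = c(min(dec$freqs), 2 - 1e-9),
           spindle = c(10, 18),
           theta = c(4, 8),
           stop("unknown band: ", band))
  } else band
  if (lim[1] > max(dec$freqs) || lim[2] < min(dec$freqs)) {
    stop("band lies outside the frequency grid")
  }
  r <- dec$residual[channel, ]
  d <- diff(r)
  is_peak <- c(FALSE, d[-length(d)] > 0 & d[-1] < 0, FALSE)
  # plateau peaks: rising into a flat top counts at the first flat sample
  flat <- c(FALSE, d[-length(d)] > 0 & d[-1] == 0, FALSE)
  is_peak <- is_peak | flat
  sel <- which(is_peak & dec$freqs >= lim[1] & dec$freqs <= lim[2] & r > 0)
  if (length(sel) == 0L) return(NULL)
  best <- sel[order(-r[sel], dec$freqs[sel])][1]
  list(freq = dec$freqs[best], amp = r[best], band = band_name,
       channel = dec$channels[channel])
}

# --- discrete prolate spheroidal (Slepian) tapers -------------------------

.dpss_cache <- new.env(parent = emptyenv())

# Tapers from the symmetric tridiagonal eigenproblem; for long windows the
# eigenvectors are computed at a reduced length and spline-interpolated
# (shape depends on the time-bandwidth product, not the sample count).
dpss_tapers <- function(n, nw, k, base_n = 512L) {
  key <- paste(n, nw, k, sep = "|")
  got <- .dpss_cache[[key]]
  if (!is.null(got)) return(got)
  n0 <- min(n, base_n)
  w <- nw / n0
  i <- 0:(n0 - 1)
  A <- matrix(0, n0, n0)
  diag(A) <- ((n0 - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n0 - 1)) * (n0 - (1:(n0 - 1))) / 2
  A[cbind(1:(n0 - 1), 2:n0)] <- off
  A[cbind(2:n0, 1:(n0 - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tap0 <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n0 == n) {
    tap <- tap0
  } else {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    tap <- apply(tap0, 2, function(v) stats::spline(x0, v, xout = x1)$y)
  }
  tap <- apply(tap, 2, function(v) v / sqrt(sum(v^2)))
  # polarity convention: positive mean for symmetric tapers
  tap <- apply(tap, 2, function(v) if (sum(v) < 0) -v else v)
  .dpss_cache[[key]] <- tap
  tap
}

#' Full-night multitaper spectrogram
#'
#' Power in 30-s epochs with 85% overlap (4.5-s steps), 0.5-30 Hz in 0.5-Hz
#' steps, using 29 Slepian (dpss) tapers, the count implied by +-0.5 Hz
#' frequency smoothing on a 30-s window (2*T*W - 1 = 29).
#'
#' @param rec a [psg_recording()].
#' @param channel channel index or label.
#' @return list with `times` (epoch centers, s), `freqs` (Hz) and `power`
#'   (epochs x freqs, log10 PSD).
#' @export
fullnight_tfr <- function(rec, channel = 1L) {
  ch <- resolve_channel(rec, channel)
  fs <- rec$fs
  win_sec <- 30; step_sec <- 4.5; smear <- 0.5
  L <- round(win_sec * fs)
  n <- n_samples(rec)
  if (n < L) stop("recording shorter than one 30-s epoch")
  n_tapers <- 2 * win_sec * smear - 1   # 29
  tap <- dpss_tapers(L, win_sec * smear, n_tapers)
  starts <- seq(1L, n - L + 1L, by = round(step_sec * fs))
  k_idx <- seq(15L, 900L, by = 15L) + 1L  # bins at 0.5..30 Hz for a 30-s window
  freqs <- (k_idx - 1L) / win_sec
  power <- matrix(NA_real_, length(starts), length(freqs))
  x <- rec$signal[ch, ]
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + L - 1L)]
    seg <- seg - mean(seg)
    sp <- Mod(stats::mvfft(tap * seg))^2
    power[i, ] <- log10(2 * rowMeans(sp)[k_idx] / fs)
  }
  list(times = (starts - 1L) / fs + win_sec / 2, freqs = freqs, power = power)
}
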