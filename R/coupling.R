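# Event-locked cross-frequency coupling: slow-oscillation phase at spindle
# peaks, circular summaries, bootstrap controls, and the SO-trough-locked
# time-frequency map.

#' Slow-oscillation phase at spindle amplitude peaks
#'
#' For each spindle-peak-locked, normalized epoch: zero-phase low-pass at
#' 2 Hz isolates the SO component, and the analytic-signal phase is read at
#' the center sample (the spindle amplitude peak).  Phase convention:
#' 0 = SO positive peak (up-state), +-pi = trough.
#'
#' @param epochs an `event_epochs` object anchored at spindle peaks
#'   (see [extract_epochs()]).
#' @param lp_hz low-pass corner isolating the SO component.
#' @return numeric vector of phases in (-pi, pi], one per epoch.
#' @export
so_phase_at_spindle_peak <- function(epochs, lp_hz = 2) {
  m <- epochs$data
  if (nrow(m) == 0L) return(numeric(0))
  ctr <- (ncol(m) + 1L) %/% 2L
  b <- fir_design(fir_order(epochs$fs, 0.5), lp_hz / (epochs$fs / 2), "low")
  so_comp <- fir_filter_zerophase_rows(m, b)
  phases <- apply(so_comp, 1, function(v) Arg(analytic_signal(v)[ctr]))
  wrap_phase(phases)
}

#' Percentage of events within the preferred phase
#'
#' Share of phases whose absolute circular distance to the preferred phase
#' is at most `radius` (default 22.5 degrees, i.e. a 45-degree window),
#' boundary inclusive.
#'
#' @param phases phase angles (radians).
#' @param preferred preferred phase (radians), e.g. [preferred_phase()].
#' @param radius half width of the window (radians).
#' @return percentage in \[0, 100\].
#' @export
pct_in_preferred <- function(phases, preferred, radius = 22.5 * pi / 180) {
  if (length(phases) == 0L) stop("no phases supplied")
  100 * mean(abs(circ_dist(phases, preferred)) <= radius + 1e-12)
}

#' Absolute circular distance of the preferred phase to the SO up-state
#'
#' Linearizes the circular preferred phase for repeated-measures testing:
#' the absolute wrapped angular distance to 0 degrees (the SO positive
#' peak), in degrees, in \[0, 180\].
#'
#' @param preferred preferred phase in radians.
#' @return distance in degrees.
#' @export
phase_distance_to_upstate <- function(preferred) {
  abs(circ_dist(preferred, 0)) * 180 / pi
}

#' Bootstrap control for event-count differences in coupling metrics
#'
#' Redraws `n_draw` events with replacement `n_boot` times and recomputes
#' the preferred phase and coupling strength for each draw, controlling
#' comparisons for differences in event number.
#'
#' @param phases phase angles (radians).
#' @param n_draw events per draw.
#' @param n_boot number of draws.
#' @param seed integer seed (reproducible draws).
#' @return object of class `bootstrap_coupling`: data.frame `draws`
#'   (`preferred_phase`, `strength`) plus summary means/SDs.
#' @export
bootstrap_coupling <- function(phases, n_draw = 500, n_boot = 100, seed = 1L) {
  if (length(phases) == 0L) stop("no phases supplied")
  set.seed(seed)
  draws <- data.frame(preferred_phase = numeric(n_boot), strength = numeric(n_boot))
  for (b in seq_len(n_boot)) {
    ph <- phases[sample.int(length(phases), n_draw, replace = TRUE)]
    z <- mean(exp(1i * ph))
    draws$preferred_phase[b] <- wrap_phase(Arg(z))
    draws$strength[b] <- Mod(z)
  }
  structure(list(draws = draws,
                 mean_strength = mean(draws$strength),
                 sd_strength = stats::sd(draws$strength),
                 mean_direction = wrap_phase(Arg(mean(exp(1i * draws$preferred_phase)))),
                 n_draw = n_draw, n_boot = n_boot, seed = seed),
            class = "bootstrap_coupling")
}

#' Event-locked coupling summary
#'
#' Convenience wrapper computing the full circular summary for a set of
#' SO phases observed at spindle peaks.
#'
#' @param phases phase angles (radians).
#' @param channel,stage labels carried through to the output.
#' @return object of class `coupling_stats`: `preferred_phase` (rad),
#'   `coupling_strength` (resultant length), `n_events`,
#'   `pct_in_preferred`, `phase_sd` (circular SD, rad).
#' @export
coupling_stats <- function(phases, channel = NA_character_, stage = "N3") {
  if (length(phases) == 0L) stop("no phases supplied")
  pp <- preferred_phase(phases)
  structure(list(
    preferred_phase = pp,
    coupling_strength = coupling_strength(phases),
    n_events = length(phases),
    pct_in_preferred = if (is.na(pp)) NA_real_ else pct_in_preferred(phases, pp),
    phase_sd = circ_sd(phases),
    channel = channel, stage = stage
  ), class = "coupling_stats")
}

#' @export
print.coupling_stats <- function(x, ...) {
  cat(sprintf(paste0("coupling_stats [%s, %s]: n=%d, preferred phase %.1f deg,",
                     " strength %.3f, %.1f%% in preferred +-22.5 deg\n"),
              x$channel, x$stage, x$n_events, x$preferred_phase * 180 / pi,
              x$coupling_strength, x$pct_in_preferred))
  invisible(x)
}

#' SO-trough-locked time-frequency representation
#'
#' Short-time power (500-ms Hann window) on normalized SO-trough-locked
#' epochs, -2 to 2 s in 50-ms steps, 5-30 Hz in 0.5-Hz steps.  The map is
#' z-scored against a bootstrapped baseline: trials are resampled with
#' replacement `n_boot` times, the trial-average power in the -2 to -1.5 s
#' window is collected per frequency (pooling the baseline time bins, so
#' the spread is on the scale of single map bins), and the resulting
#' mean/SD per frequency standardize the map.
#'
#' @param epochs an `event_epochs` object anchored at SO troughs, +-2.5 s.
#' @param seed integer seed for the baseline bootstrap.
#' @param n_boot baseline bootstrap iterations.
#' @return list with `times` (s, relative to the trough), `freqs` (Hz) and
#'   `z` (times x freqs z-scored power map).
#' @export
so_locked_tfr <- function(epochs, seed = 1L, n_boot = 10000) {
  m <- epochs$data
  if (nrow(m) < 10L) stop("need at least 10 epochs")
  fs <- epochs$fs
  ctr <- (ncol(m) + 1L) %/% 2L
  win <- round(0.5 * fs)
  if (win %% 2L == 1L) win <- win + 1L
  half <- win %/% 2L
  taper <- hann_window(win)
  times <- seq(-2, 2, by = 0.05)
  freqs <- seq(5, 30, by = 0.5)
  nfft <- stats::nextn(max(win, 2L * fs), c(2L, 3L, 5L))
  fbin <- round(freqs * nfft / fs) + 1L
  n_tr <- nrow(m)
  pow <- array(NA_real_, c(n_tr, length(times), length(freqs)))
  for (tr in seq_len(n_tr)) {
    for (ti in seq_along(times)) {
      c0 <- ctr + round(times[ti] * fs)
      seg <- m[tr, (c0 - half + 1L):(c0 + half)] * taper
      sp <- Mod(stats::fft(c(seg, rep(0, nfft - win))))^2
      pow[tr, ti, ] <- sp[fbin]
    }
  }
  # bootstrap baseline: resample trials with replacement, average across
  # trials per baseline time bin, and pool the baseline bins into the
  # bootstrap distribution so its SD is on the scale of single map bins
  bl_t <- which(times >= -2 & times <= -1.5)
  bl <- matrix(pow[, bl_t, , drop = FALSE], nrow = n_tr)  # trials x (bins*freqs)
  set.seed(seed)
  idx <- matrix(sample.int(n_tr, n_boot * n_tr, replace = TRUE), n_boot, n_tr)
  sel <- matrix(0, n_boot, n_tr)
  for (b in seq_len(n_boot)) sel[b, ] <- tabulate(idx[b, ], nbins = n_tr)
  boot_means <- (sel %*% bl) / n_tr              # n_boot x (bins*freqs)
  dim(boot_means) <- c(n_boot * length(bl_t), length(freqs))
  mu <- colMeans(boot_means)
  sdv <- apply(boot_means, 2, stats::sd)
  if (any(sdv <= 0)) stop("degenerate baseline: zero bootstrap variance")
  avg <- apply(pow, c(2, 3), mean)               # times x freqs
  z <- sweep(sweep(avg, 2, mu, "-"), 2, sdv, "/")
  list(times = times, freqs = freqs, z = z)
}
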