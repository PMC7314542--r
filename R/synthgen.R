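# Synthetic polysomnography with full ground truth: 1/f^beta background,
# injected slow-oscillation cycles, spindle bursts phase-coupled to the SO
# via a von Mises law, stage structure, and paired longitudinal cohorts with
# a behavioral readout.  Every stochastic element is reproducible by seed.

# deterministic sub-seed for a named stage of a computation (stays < 2^31)
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Generate 1/f^beta fractal noise
#'
#' Gaussian noise synthesized in the frequency domain with one-sided power
#' spectral density `10^offset * f^(-beta)` (units^2/Hz), the spectral model
#' of the aperiodic EEG background.
#'
#' @param n_samples length of the signal (>= fs).
#' @param fs sampling rate (Hz).
#' @param beta spectral exponent, in \[0, 3\]; 0 gives white noise.
#' @param offset log10 power spectral density at 1 Hz.
#' @param seed optional integer seed (deterministic output).
#' @return numeric vector of length `n_samples`.
#' @export
gen_fractal_noise <- function(n_samples, fs, beta, offset = 0, seed = NULL) {
  if (beta < 0 || beta > 3) stop("beta must lie in [0, 3]")
  if (n_samples < fs) stop("need at least one second of samples")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples)
  kmax <- n %/% 2L
  f <- (1:kmax) * fs / n
  s2 <- 0.5 * 10^offset * f^(-beta)        # two-sided PSD
  amp <- sqrt(n * fs * s2)
  X <- complex(real = numeric(n), imaginary = numeric(n))
  if (n %% 2L == 0L) {
    kpos <- 1:(kmax - 1L)
    X[kpos + 1L] <- amp[kpos] * complex(real = stats::rnorm(kmax - 1L),
                                        imaginary = stats::rnorm(kmax - 1L)) / sqrt(2)
    X[kmax + 1L] <- amp[kmax] * stats::rnorm(1L)
    X[n - kpos + 1L] <- Conj(X[kpos + 1L])
  } else {
    kpos <- 1:kmax
    X[kpos + 1L] <- amp[kpos] * complex(real = stats::rnorm(kmax),
                                        imaginary = stats::rnorm(kmax)) / sqrt(2)
    X[n - kpos + 1L] <- Conj(X[kpos + 1L])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# offset giving a target time-domain standard deviation for gen_fractal_noise
fractal_offset_for_sd <- function(sd, beta, fs, n_samples) {
  n <- as.integer(n_samples)
  kmax <- n %/% 2L
  f <- (1:kmax) * fs / n
  # variance at offset 0: both spectral sides
  w <- rep(2, kmax)
  if (n %% 2L == 0L) w[kmax] <- 1
  var0 <- (fs / n) * sum(w * 0.5 * f^(-beta))
  log10(sd^2 / var0)
}

#' Canonical slow-oscillation waveform
#'
#' One biphasic cycle: negative trough (down-state) followed by a positive
#' peak (up-state), zero-valued at both ends, with the requested
#' trough-to-peak amplitude.  The trough sits at 1/4 of the duration.
#'
#' @param duration cycle length in seconds, in \[0.8, 2\] (the detection
#'   criterion range).
#' @param amplitude trough-to-peak amplitude in microvolts.
#' @param fs sampling rate (Hz).
#' @return numeric vector of `round(duration*fs) + 1` samples.
#' @export
make_so_waveform <- function(duration, amplitude, fs) {
  if (duration < 0.8 || duration > 2) stop("duration must lie in [0.8, 2] s")
  L <- round(duration * fs)
  w <- -sin(2 * pi * (0:L) / L)
  # rescale so the sampled trough-to-peak is exactly `amplitude`
  w * (amplitude / (max(w) - min(w)))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Default parameter set for [gen_coupled_recording()]
#'
#' The defaults define the generator's standing study conditions: a
#' slow-wave-sleep-rich recording (alternating N3/N2 blocks), a 1/f^2
#' background of 15 uV with a higher N3 offset, slow oscillations of
#' 75-300 uV at 10/min in N3 (child NREM3 is SO-dense), spindles of
#' 10-40 uV lasting 0.8-1.8 s, most slow oscillations hosting a coupled
#' spindle, plus sparse uncoupled spindles (more in N2, where isolated
#' spindles dominate).
#'
#' @param ... overrides for any listed field.
#' @export
coupled_spec <- function(...) {
  spec <- list(
    fs = 512, channels = "Cz",
    n3_min = 10, n2_min = 5, block_min = 5,
    beta = 2, background_sd = 15, n2_offset_drop = 0.3,
    so_rate_n3 = 10, so_rate_n2 = 2,
    so_dur = c(0.9, 1.4), so_amp = c(75, 300),
    spindle_freq = 13, spindle_dur = c(0.8, 1.8), spindle_amp = c(10, 40),
    p_coupled = 0.9, uncoupled_rate_n3 = 1, uncoupled_rate_n2 = 2,
    uncoupled_avoid_so = TRUE, min_gap = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(spec))
  if (length(unknown)) stop("unknown spec field(s): ", paste(unknown, collapse = ", "))
  spec[names(ov)] <- ov
  spec
}

# renewal-process event starts within [t0, t1]: gaps = min_gap + Exp
place_events <- function(t0, t1, rate_per_min, dur_range, min_gap) {
  if (rate_per_min <= 0) return(data.frame(start = numeric(0), duration = numeric(0)))
  mean_dur <- mean(dur_range)
  spacing <- 60 / rate_per_min
  if (spacing < mean_dur + min_gap + 0.05) {
    stop("requested event rate does not fit: mean spacing ", round(spacing, 2),
         " s < duration + minimum gap")
  }
  mean_exp <- spacing - mean_dur - min_gap
  starts <- numeric(0); durs <- numeric(0)
  t <- t0
  repeat {
    gap <- min_gap + stats::rexp(1, 1 / mean_exp)
    d <- stats::runif(1, dur_range[1], dur_range[2])
    s <- t + gap
    if (s + d > t1 - 0.1) break
    starts <- c(starts, s); durs <- c(durs, d)
    t <- s + d
  }
  data.frame(start = starts, duration = durs)
}

#' Generate a recording with phase-coupled SO and spindle events
#'
#' Builds `1/f^beta` background noise, injects slow-oscillation cycles at
#' stage-dependent rates, and places spindle bursts whose centers are
#' phase-targeted on the noise-free SO component: for each coupled spindle a
#' phase `phi ~ vonMises(mu, kappa)` is drawn and the burst is centered at
#' the sample where the Hilbert phase of the clean SO component attains
#' `phi`, so the ground truth is exact and independent of any detector.
#' Uncoupled spindles are placed uniformly (by default outside SO windows).
#'
#' @param spec parameter list from [coupled_spec()].
#' @param mu mean coupling phase (radians; 0 = SO positive peak).
#' @param kappa von Mises concentration (>= 0); 0 = no phase preference.
#' @param seed integer seed.
#' @return list with `recording` (a [psg_recording()]) and `truth`
#'   (fractal exponents/offsets, SO and spindle event tables with true
#'   phases, mu, kappa, seed).
#' @export
gen_coupled_recording <- function(spec = coupled_spec(), mu = 33.5 * pi / 180,
                                  kappa = 4, seed = 1L) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (spec$spindle_freq < 10 || spec$spindle_freq > 18) {
    stop("spindle frequency must lie in [10, 18] Hz")
  }
  fs <- spec$fs
  # hypnogram: alternate N3/N2 blocks until both quotas are filled
  ep_per_block <- round(spec$block_min * 60 / EPOCH_SEC)
  quota <- c(N3 = round(spec$n3_min * 60 / EPOCH_SEC),
             N2 = round(spec$n2_min * 60 / EPOCH_SEC))
  stages <- character(0); turn <- "N3"
  while (any(quota > 0)) {
    take <- min(ep_per_block, quota[[turn]])
    if (take > 0) {
      stages <- c(stages, rep(turn, take))
      quota[[turn]] <- quota[[turn]] - take
    }
    turn <- if (turn == "N3") "N2" else "N3"
  }
  n <- length(stages) * EPOCH_SEC * fs
  hyp <- new_hypnogram(stages)
  blocks <- data.frame(stage = rle(stages)$values,
                       len = rle(stages)$lengths)
  blocks$end_ep <- cumsum(blocks$len)
  blocks$t0 <- (blocks$end_ep - blocks$len) * EPOCH_SEC
  blocks$t1 <- blocks$end_ep * EPOCH_SEC

  n_ch <- length(spec$channels)
  sig <- matrix(0, n_ch, n)
  so_all <- list(); sp_all <- list()
  offset <- if (spec$background_sd > 0) {
    fractal_offset_for_sd(spec$background_sd, max(spec$beta, 1e-6), fs, n)
  } else -Inf  # noise-free recording (ground-truth phase checks)
  t_samp <- (seq_len(n) - 1) / fs
  stage_of_samp <- stages[pmin((seq_len(n) - 1L) %/% (EPOCH_SEC * fs) + 1L,
                               length(stages))]

  for (ci in seq_len(n_ch)) {
    set.seed(derive_seed(seed, paste0("chan", ci)))
    bg <- if (is.finite(offset)) gen_fractal_noise(n, fs, spec$beta, offset)
          else numeric(n)
    # stage-dependent offset: N2 background sits lower on the log-power axis
    bg[stage_of_samp == "N2"] <- bg[stage_of_samp == "N2"] *
      10^(-spec$n2_offset_drop / 2)

    # SO gaps leave room for a worst-case phase-targeted spindle on each
    # side (max spindle half-duration twice, plus the spindle gap);
    # otherwise collisions would preferentially reject early-phase
    # spindles and bias the attained phase law away from von Mises
    so_gap <- spec$min_gap + spec$spindle_dur[2]
    so <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(bi) {
      rate <- if (blocks$stage[bi] == "N3") spec$so_rate_n3 else spec$so_rate_n2
      ev <- place_events(blocks$t0[bi], blocks$t1[bi], rate, spec$so_dur, so_gap)
      if (nrow(ev)) ev$stage <- blocks$stage[bi]
      ev
    }))
    so$amplitude <- stats::runif(nrow(so), spec$so_amp[1], spec$so_amp[2])
    so$trough_time <- so$start + so$duration / 4
    so_comp <- numeric(n)
    for (k in seq_len(nrow(so))) {
      w <- make_so_waveform(so$duration[k], so$amplitude[k], fs)
      i0 <- round(so$start[k] * fs) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      so_comp[idx] <- so_comp[idx] + w
    }
    # SO phase is defined on the < 2 Hz component (the measurement
    # convention); filtering the clean trace keeps ground truth and
    # event-locked estimates on one convention
    ph <- Arg(analytic_signal(lowpass_filter(so_comp, fs, 2)))

    # coupled spindles: one per hosting SO, centered where the clean SO
    # phase attains the drawn von Mises phase
    occupied <- matrix(numeric(0), ncol = 2)  # placed spindle intervals
    sp <- list()
    for (k in seq_len(nrow(so))) {
      if (stats::runif(1) > spec$p_coupled) next
      phi <- rvonmises(1L, mu, kappa)
      i0 <- round(so$start[k] * fs) + 1L
      i1 <- min(round((so$start[k] + so$duration[k]) * fs) + 1L, n)
      seg <- i0:i1
      ctr <- seg[which.min(abs(circ_dist(ph[seg], phi)))]
      d <- stats::runif(1, spec$spindle_dur[1], spec$spindle_dur[2])
      lo <- (ctr - 1) / fs - d / 2; hi <- lo + d
      if (lo < 0.5 || hi > n / fs - 0.5) next
      if (nrow(occupied) &&
          any(lo < occupied[, 2] + spec$min_gap & hi > occupied[, 1] - spec$min_gap)) next
      occupied <- rbind(occupied, c(lo, hi))
      sp[[length(sp) + 1L]] <- data.frame(
        peak_time = (ctr - 1) / fs, duration = d,
        freq = spec$spindle_freq,
        amplitude = stats::runif(1, spec$spindle_amp[1], spec$spindle_amp[2]),
        phase = ph[ctr], coupled = TRUE, stage = so$stage[k])
    }
    # uncoupled spindles: uniform within stage, optionally outside SO windows
    for (st in c("N3", "N2")) {
      rate <- if (st == "N3") spec$uncoupled_rate_n3 else spec$uncoupled_rate_n2
      st_min <- sum(stages == st) * EPOCH_SEC / 60
      n_unc <- stats::rpois(1, rate * st_min)
      st_blocks <- blocks[blocks$stage == st, , drop = FALSE]
      tries <- 0L
      while (n_unc > 0L && tries < 200L * n_unc) {
        tries <- tries + 1L
        bi <- sample.int(nrow(st_blocks), 1L, prob = st_blocks$len)
        d <- stats::runif(1, spec$spindle_dur[1], spec$spindle_dur[2])
        ctr_t <- stats::runif(1, st_blocks$t0[bi] + d, st_blocks$t1[bi] - d)
        lo <- ctr_t - d / 2; hi <- ctr_t + d / 2
        if (spec$uncoupled_avoid_so &&
            any(lo < so$start + so$duration + 0.5 & hi > so$start - 0.5)) next
        if (nrow(occupied) &&
            any(lo < occupied[, 2] + spec$min_gap & hi > occupied[, 1] - spec$min_gap)) next
        occupied <- rbind(occupied, c(lo, hi))
        ctr <- round(ctr_t * fs) + 1L
        near <- max(1L, ctr - fs):min(n, ctr + fs)
        sp[[length(sp) + 1L]] <- data.frame(
          peak_time = (ctr - 1) / fs, duration = d, freq = spec$spindle_freq,
          amplitude = stats::runif(1, spec$spindle_amp[1], spec$spindle_amp[2]),
          phase = if (max(abs(so_comp[near])) > 1e-9) ph[ctr] else NA_real_,
          coupled = FALSE, stage = st)
        n_unc <- n_unc - 1L
      }
    }
    sp <- if (length(sp)) do.call(rbind, sp) else
      data.frame(peak_time = numeric(0), duration = numeric(0), freq = numeric(0),
                 amplitude = numeric(0), phase = numeric(0), coupled = logical(0),
                 stage = character(0))
    sp <- sp[order(sp$peak_time), , drop = FALSE]
    rownames(sp) <- NULL
    sp_comp <- numeric(n)
    for (k in seq_len(nrow(sp))) {
      L <- round(sp$duration[k] * fs)
      ctr <- round(sp$peak_time[k] * fs) + 1L
      idx <- (ctr - L %/% 2L):(ctr - L %/% 2L + L - 1L)
      tt <- (idx - ctr) / fs
      psi <- stats::runif(1, 0, 2 * pi)
      sp_comp[idx] <- sp_comp[idx] +
        sp$amplitude[k] * hann_window(L) * cos(2 * pi * sp$freq[k] * tt + psi)
    }
    sig[ci, ] <- bg + so_comp + sp_comp
    so$channel <- spec$channels[ci]
    sp$channel <- spec$channels[ci]
    so_all[[ci]] <- so
    sp_all[[ci]] <- sp
  }

  rec <- psg_recording(sig, fs, spec$channels, hyp)
  truth <- list(
    beta = spec$beta, offset = offset,
    so = do.call(rbind, so_all), spindles = do.call(rbind, sp_all),
    mu = mu, kappa = kappa, seed = seed, spec = spec
  )
  list(recording = rec, truth = truth)
}

#' Specification of a paired longitudinal synthetic cohort
#'
#' Each subject is recorded at two timepoints ("t1" = childhood, "t2" =
#' adolescence) with subject-specific parameters drawn from the listed
#' distributions; delayed recall at t2 follows the linear model
#' `recall = a + b*(kappa_t2 - kappa_t1) + noise`, tying the behavioral
#' change to the coupling-concentration change.  Timepoint contrasts follow
#' the developmental direction: spindle peak frequency rises, the fractal
#' background flattens and SO amplitude drops from t1 to t2, while the
#' coupling concentration doubles.
#'
#' @param ... overrides for any listed field.
#' @export
cohort_spec <- function(...) {
  spec <- list(
    n_subjects = 14,
    montage = c("F3", "Fz"),
    fs = 128, n3_min = 7, n2_min = 0,
    spindle_freq_mean = c(t1 = 11.5, t2 = 13.3), spindle_freq_sd = 0.5,
    beta = c(t1 = 2.2, t2 = 1.8),
    so_rate = c(t1 = 10, t2 = 10),
    so_amp_lo = c(t1 = 100, t2 = 75), so_amp_hi = c(t1 = 300, t2 = 250),
    kappa_logmean = c(t1 = log(0.7), t2 = log(2.2)), kappa_logsd = 0.7,
    mu = 33.5 * pi / 180,
    p_coupled = 0.9, uncoupled_rate_n3 = 1,
    behavior_a = 55, behavior_b = 2, behavior_noise_sd = 2
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(spec))
  if (length(unknown)) stop("unknown cohort field(s): ", paste(unknown, collapse = ", "))
  spec[names(ov)] <- ov
  if (spec$n_subjects < 2) stop("n_subjects must be >= 2")
  if (spec$behavior_noise_sd < 0) stop("behavior noise SD must be >= 0")
  spec
}

#' Generate a paired longitudinal cohort with behavior
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `subjects` (per subject, `t1`/`t2` each holding
#'   `recording` + `truth`), `behavior` (subject x timepoint immediate and
#'   delayed recall percentages) and `params` (the drawn subject-level
#'   parameters, including the true kappa change).
#' @export
gen_cohort <- function(spec = cohort_spec(), seed = 1L) {
  subjects <- vector("list", spec$n_subjects)
  params <- data.frame(subject = seq_len(spec$n_subjects))
  set.seed(derive_seed(seed, "cohort-params"))
  for (tp in c("t1", "t2")) {
    params[[paste0("kappa_", tp)]] <-
      exp(stats::rnorm(spec$n_subjects, spec$kappa_logmean[[tp]], spec$kappa_logsd))
    params[[paste0("spindle_freq_", tp)]] <-
      pmin(pmax(stats::rnorm(spec$n_subjects, spec$spindle_freq_mean[[tp]],
                             spec$spindle_freq_sd), 10.5), 17.5)
  }
  for (s in seq_len(spec$n_subjects)) {
    subjects[[s]] <- lapply(stats::setNames(c("t1", "t2"), c("t1", "t2")), function(tp) {
      cs <- coupled_spec(
        fs = spec$fs, channels = spec$montage,
        n3_min = spec$n3_min, n2_min = spec$n2_min,
        beta = spec$beta[[tp]],
        so_rate_n3 = spec$so_rate[[tp]],
        so_amp = c(spec$so_amp_lo[[tp]], spec$so_amp_hi[[tp]]),
        spindle_freq = params[[paste0("spindle_freq_", tp)]][s],
        p_coupled = spec$p_coupled,
        uncoupled_rate_n3 = spec$uncoupled_rate_n3
      )
      gen_coupled_recording(cs, mu = spec$mu,
                            kappa = params[[paste0("kappa_", tp)]][s],
                            seed = derive_seed(seed, sprintf("subj%d-%s", s, tp)))
    })
  }
  set.seed(derive_seed(seed, "cohort-behavior"))
  dkappa <- params$kappa_t2 - params$kappa_t1
  imm_t1 <- stats::rnorm(spec$n_subjects, 45, 2)
  del_t1 <- imm_t1 - abs(stats::rnorm(spec$n_subjects, 5, 1))
  del_t2 <- spec$behavior_a + spec$behavior_b * dkappa +
    stats::rnorm(spec$n_subjects, 0, spec$behavior_noise_sd)
  imm_t2 <- del_t2 + abs(stats::rnorm(spec$n_subjects, 5, 2))
  clamp <- function(x) pmin(pmax(x, 0), 100)
  behavior <- rbind(
    data.frame(subject = params$subject, timepoint = "t1",
               immediate = clamp(imm_t1), delayed = clamp(del_t1)),
    data.frame(subject = params$subject, timepoint = "t2",
               immediate = clamp(imm_t2), delayed = clamp(del_t2))
  )
  list(subjects = subjects, behavior = behavior, params = params, spec = spec,
       seed = seed)
}
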