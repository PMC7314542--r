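# Property-based validation runs: each function regenerates its synthetic
# inputs from a seed, executes the relevant pipeline stages, and returns the
# measured quantities.  Used by the test suite and by scripts/acceptance.R.
# All are internal; they exist so that both consumers measure the same thing.

# IRASA on pure 1/f^beta noise: fractal slope recovery and residual bias.
# 60-s recordings at 128 Hz, `n_seeds` per exponent.
validate_irasa_recovery <- function(seed = 1L, n_seeds = 20L,
                                    betas = c(0, 1, 2)) {
  fs <- 128
  slope_err <- numeric(length(betas))
  resid_bias <- numeric(length(betas))
  for (bi in seq_along(betas)) {
    resids <- NULL; slopes <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      x <- gen_fractal_noise(60 * fs, fs, betas[bi], 0,
                             seed = derive_seed(seed, sprintf("irasa-%d-%d", bi, s)))
      dec <- irasa(psg_recording(matrix(x, 1), fs), rep(TRUE, length(x)))
      k <- dec$freqs >= 2 & dec$freqs <= 25
      slopes[s] <- unname(stats::coef(
        stats::lm(dec$fractal[1, k] ~ log10(dec$freqs[k])))[2])
      resids <- if (is.null(resids)) dec$residual[1, k] else
        resids + dec$residual[1, k]
    }
    slope_err[bi] <- abs(mean(slopes) + betas[bi])
    resid_bias[bi] <- mean(abs(resids / n_seeds))
  }
  list(slope_err = slope_err, resid_bias = resid_bias, betas = betas,
       n = n_seeds)
}

# Oscillatory peak recovery: tones at 12.6 and 0.8 Hz on 1/f background,
# recovered from the IRASA residual within +-0.15 Hz.
validate_peak_recovery <- function(seed = 1L, n_seeds = 20L,
                                   f_spindle = 12.6, f_so = 0.8) {
  fs <- 128
  ok_sp <- logical(n_seeds); ok_so <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    x <- gen_fractal_noise(60 * fs, fs, 1, 0,
                           seed = derive_seed(seed, paste0("peak-", s)))
    tt <- (0:(60 * fs - 1)) / fs
    amp <- stats::sd(x)
    x <- x + amp * sin(2 * pi * f_spindle * tt) +
      0.8 * amp * sin(2 * pi * f_so * tt)
    dec <- irasa(psg_recording(matrix(x, 1), fs), rep(TRUE, length(x)))
    pk_sp <- find_band_peak(dec, "spindle")
    pk_so <- find_band_peak(dec, "so")
    ok_sp[s] <- !is.null(pk_sp) && abs(pk_sp$freq - f_spindle) <= 0.15
    ok_so[s] <- !is.null(pk_so) && abs(pk_so$freq - f_so) <= 0.15
  }
  list(rate_spindle = mean(ok_sp), rate_so = mean(ok_so), n = n_seeds)
}

# Detector fidelity on default-SNR recordings (10 min each): pooled
# precision/recall against ground truth.  The SO detector is a
# top-quartile-amplitude detector, so its recall reference is the top
# amplitude quartile of injected events; precision is scored against all
# injected events.  Matching: SO trough +-0.3 s, spindle peak +-0.5 s.
validate_detectors <- function(seed = 1L, n_seeds = 10L) {
  acc <- c(so_prec_tp = 0, so_det = 0, so_rec_tp = 0, so_ref = 0,
           sp_prec_tp = 0, sp_det = 0, sp_rec_tp = 0, sp_ref = 0)
  durations_ok <- TRUE
  for (s in seq_len(n_seeds)) {
    cs <- coupled_spec(fs = 128, n3_min = 7, n2_min = 3)
    g <- gen_coupled_recording(cs, kappa = 4,
                               seed = derive_seed(seed, paste0("det-", s)))
    mask <- stage_sample_mask(g$recording, c("N2", "N3"))
    recz <- znormalize(g$recording, mask)
    so <- detect_so(recz, 1, mask)
    sp <- detect_spindles(recz, 1, mask, peak_freq = 13)
    durations_ok <- durations_ok &&
      all(so$duration >= 0.8 & so$duration <= 2) &&
      all(sp$duration >= 0.5 & sp$duration <= 3)
    tso <- g$truth$so; tsp <- g$truth$spindles
    top <- tso$trough_time[tso$amplitude >
                             stats::quantile(tso$amplitude, 0.75)]
    s_so <- score_detections(so$trough_time, top, tol = 0.3,
                             precision_reference = tso$trough_time)
    s_sp <- score_detections(sp$peak_time, tsp$peak_time, tol = 0.5)
    acc <- acc + c(s_so$precision * nrow(so), nrow(so),
                   s_so$recall * length(top), length(top),
                   s_sp$precision * nrow(sp), nrow(sp),
                   s_sp$recall * nrow(tsp), nrow(tsp))
  }
  list(so_precision = acc[["so_prec_tp"]] / acc[["so_det"]],
       so_recall = acc[["so_rec_tp"]] / acc[["so_ref"]],
       spindle_precision = acc[["sp_prec_tp"]] / acc[["sp_det"]],
       spindle_recall = acc[["sp_rec_tp"]] / acc[["sp_ref"]],
       durations_ok = durations_ok, n = n_seeds)
}

# Full-pipeline coupling recovery: strength within the von Mises closed
# form and preferred phase within +-10 degrees of mu, >= 300 coupled
# events.  The recordings are fully coupled (no uncoupled spindles): the
# closed form describes the coupled population, and at kappa = 0 the
# finite-sample resultant floor sqrt(pi)/(2 sqrt(n)) sets the noise scale,
# so a long N3 stretch keeps it well inside the tolerance.
validate_coupling_recovery <- function(seed = 1L, kappas = c(0, 1, 2, 4)) {
  cfg <- pipeline_config(spectral_max_sec = 60, bootstrap_n_boot = 0)
  mu <- 33.5 * pi / 180
  strength <- numeric(length(kappas))
  phase_err <- rep(NA_real_, length(kappas))
  n_events <- integer(length(kappas))
  for (i in seq_along(kappas)) {
    cs <- coupled_spec(fs = 128, n3_min = 60, n2_min = 0, p_coupled = 1,
                       uncoupled_rate_n3 = 0, uncoupled_rate_n2 = 0)
    g <- gen_coupled_recording(cs, mu = mu, kappa = kappas[i],
                               seed = derive_seed(seed, paste0("kap-", i)))
    res <- run_subject(g$recording, cfg, seed = seed)
    strength[i] <- res$summary$coupling_strength
    n_events[i] <- sum(g$truth$spindles$coupled)
    if (kappas[i] >= 2) {
      phase_err[i] <- abs(circ_dist(res$summary$preferred_phase, mu)) * 180 / pi
    }
  }
  list(kappas = kappas, strength = strength,
       strength_err = abs(strength - vonmises_resultant(kappas)),
       phase_err = phase_err, n_coupled = n_events,
       monotone = all(diff(strength) > 0))
}

# Closed-form circular checks: expected uniform resultant at n = 500 and
# the 45-degree-window expectation under uniformity.
validate_circular_closed_forms <- function(seed = 1L, n_rep = 200L) {
  set.seed(derive_seed(seed, "circ"))
  r <- vapply(seq_len(n_rep), function(i)
    coupling_strength(stats::runif(500, -pi, pi)), 0)
  pct <- pct_in_preferred(stats::runif(1e4, -pi, pi), 1.0)
  list(mean_resultant = mean(r), expected_resultant = sqrt(pi) / (2 * sqrt(500)),
       pct_uniform = pct, n = 500L)
}

# Cluster permutation calibration: family-wise type-I error over null
# simulations and power for a 1-SD shift in bins 10-15 (20 subjects x 30
# bins).
validate_cluster_calibration <- function(seed = 1L, n_null = 200L,
                                         n_power = 100L) {
  set.seed(derive_seed(seed, "clus-null"))
  rej <- vapply(seq_len(n_null), function(i) {
    a <- matrix(stats::rnorm(20 * 30), 20)
    b <- matrix(stats::rnorm(20 * 30), 20)
    cr <- cluster_permutation_paired(a, b, n_perm = 1000,
                                     seed = sample.int(2^30, 1))
    any(cr$clusters$significant)
  }, TRUE)
  set.seed(derive_seed(seed, "clus-pow"))
  hit <- vapply(seq_len(n_power), function(i) {
    a <- matrix(stats::rnorm(20 * 30), 20)
    b <- a + matrix(stats::rnorm(20 * 30), 20)
    b[, 10:15] <- b[, 10:15] + 1
    cr <- cluster_permutation_paired(b, a, n_perm = 1000,
                                     seed = sample.int(2^30, 1))
    sig <- which(cr$clusters$significant & cr$clusters$sign > 0)
    length(sig) > 0 &&
      any(vapply(sig, function(j) any(cr$members[[j]] %in% 10:15), TRUE))
  }, TRUE)
  list(fwer = mean(rej), power = mean(hit), n_null = n_null, n_power = n_power)
}

# One synthetic longitudinal cohort through the full pipeline; returns
# whether a significant positive frontal cluster was found.
run_cohort_once <- function(seed, effect = TRUE) {
  spec <- if (effect) {
    # the favorable recovery regime: strong behavioral slope, small noise,
    # fully coupled spindles
    cohort_spec(behavior_b = 5, behavior_noise_sd = 0.5,
                p_coupled = 1, uncoupled_rate_n3 = 0)
  } else {
    cohort_spec(behavior_b = 0, behavior_noise_sd = 0.5,
                p_coupled = 1, uncoupled_rate_n3 = 0)
  }
  coh <- gen_cohort(spec, seed = seed)
  cfg <- pipeline_config(spectral_max_sec = 20, bootstrap_n_boot = 0)
  r1 <- lapply(coh$subjects, function(s) run_subject(s$t1$recording, cfg, seed = 1))
  r2 <- lapply(coh$subjects, function(s) run_subject(s$t2$recording, cfg, seed = 1))
  names(r1) <- names(r2) <- as.character(seq_along(r1))
  cr <- run_cohort(r1, r2, coh$behavior, cfg, seed = seed)
  sig <- cr$clusters$clusters
  pos <- which(sig$significant & sig$sign > 0)
  frontal <- any(vapply(pos, function(i)
    any(c("F3", "Fz") %in%
          colnames(cr$delta_strength)[cr$clusters$members[[i]]]), TRUE))
  list(frontal = frontal, rho = cr$rho)
}

# Cohort-level recovery: detection rate of the built-in coupling-change ->
# recall-change effect, and the false-positive rate under b = 0.
validate_cohort_recovery <- function(seed = 1L, n_cohorts = 20L) {
  eff <- vapply(seq_len(n_cohorts), function(i)
    run_cohort_once(derive_seed(seed, paste0("coh-eff-", i)))$frontal, TRUE)
  nul <- vapply(seq_len(n_cohorts), function(i)
    run_cohort_once(derive_seed(seed, paste0("coh-nul-", i)),
                    effect = FALSE)$frontal, TRUE)
  list(detection_rate = mean(eff), null_rate = mean(nul), n = n_cohorts)
}

# Determinism: identical seeds give identical pipeline outputs and
# byte-identical result files.
validate_determinism <- function(seed = 1L) {
  cs <- coupled_spec(fs = 128, n3_min = 4, n2_min = 0, channels = "Cz")
  g1 <- gen_coupled_recording(cs, kappa = 2, seed = derive_seed(seed, "det"))
  g2 <- gen_coupled_recording(cs, kappa = 2, seed = derive_seed(seed, "det"))
  cfg <- pipeline_config(spectral_max_sec = 20, bootstrap_n_boot = 50)
  r1 <- run_subject(g1$recording, cfg, seed = seed)
  r2 <- run_subject(g2$recording, cfg, seed = seed)
  d1 <- tempfile(); d2 <- tempfile()
  write_subject_result(r1, d1)
  write_subject_result(r2, d2)
  files_equal <- all(vapply(list.files(d1), function(f) {
    identical(unname(tools::md5sum(file.path(d1, f))),
              unname(tools::md5sum(file.path(d2, f))))
  }, TRUE))
  unlink(c(d1, d2), recursive = TRUE)
  list(generator_identical = identical(g1$recording$signal, g2$recording$signal),
       pipeline_identical = identical(r1$summary, r2$summary) &&
         identical(r1$bootstrap$Cz$draws, r2$bootstrap$Cz$draws),
       files_identical = files_equal)
}
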