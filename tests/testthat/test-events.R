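# Individualized SO and spindle detection, epochs, density, co-occurrence.

# contiguous SO cycles of increasing amplitude embedded in a quiet carrier
so_staircase_rec <- function(n_cycles = 40, fs = 128) {
  dur <- 1.25
  amps <- seq(20, 215, length.out = n_cycles)
  x <- c(rep(0, 5 * fs))
  for (a in amps) x <- c(x, make_so_waveform(dur, a, fs)[-1])
  x <- c(x, rep(0, 5 * fs))
  # tiny carrier avoids degenerate all-zero stretches outside the cycles
  x <- x + 0.01 * sin(2 * pi * 0.5 * seq_along(x) / fs)
  n_ep <- ceiling(length(x) / (30 * fs))
  x <- c(x, rep(0, n_ep * 30 * fs - length(x)))
  list(rec = psg_recording(matrix(x, 1), fs, hypnogram = rep("N3", n_ep)),
       amps = amps, dur = dur, t0 = 5)
}

test_that("SO detector keeps exactly the top-quartile candidates", {
  st <- so_staircase_rec(40)
  ev <- detect_so(st$rec, 1, rep(TRUE, ncol(st$rec$signal)))
  expect_equal(nrow(ev), 10)                      # > 75th pct of 40 candidates
  # the 10 largest injected cycles, in order
  exp_troughs <- st$t0 + (30:39) * st$dur + st$dur / 4
  expect_equal(sort(ev$trough_time), sort(exp_troughs), tolerance = 0.05)
  expect_true(all(ev$duration >= 0.8 & ev$duration <= 2))
  expect_true(all(ev$amplitude > 0))
  # threshold monotonicity: stricter percentile, never more events
  ev90 <- detect_so(st$rec, 1, rep(TRUE, ncol(st$rec$signal)), percentile = 90)
  expect_lte(nrow(ev90), nrow(ev))
})

test_that("SO detector rejects sub-criterion half-waves", {
  fs <- 128
  x <- rep(0, 90 * fs)
  # a 0.4-s full cycle (below the 0.8-s criterion)
  w <- -100 * sin(2 * pi * (0:(0.4 * fs)) / (0.4 * fs))
  x[(10 * fs):(10 * fs + length(w) - 1)] <- w
  x <- x + 0.01 * sin(2 * pi * 0.5 * seq_along(x) / fs)
  rec <- psg_recording(matrix(x, 1), fs, hypnogram = rep("N3", 3))
  ev <- detect_so(rec, 1, rep(TRUE, length(x)))
  expect_false(any(abs(ev$trough_time - 10.1) < 0.3))
})

test_that("SO trough timing matches ground truth on synthetic recordings", {
  cs <- coupled_spec(fs = 128, n3_min = 5, n2_min = 0, background_sd = 3)
  g <- gen_coupled_recording(cs, kappa = 4, seed = 3)
  mask <- stage_sample_mask(g$recording, "N3")
  ev <- detect_so(znormalize(g$recording, mask), 1, mask)
  dmin <- vapply(ev$trough_time,
                 function(t) min(abs(g$truth$so$trough_time - t)), 0)
  expect_true(all(dmin <= 0.05))
})

test_that("spindle detector finds an isolated burst at its envelope peak", {
  fs <- 128
  # deterministic construction: a 13-Hz carrier whose amplitude profile
  # pins the 75th-percentile threshold at 3, plus one Hann burst
  burst_rec <- function(dur_s) {
    n <- 120 * fs
    amp <- rep(1, n)
    amp[seq_len(round(0.3 * n)) + round(0.7 * n) - 1L] <- 3  # top 30% at 3
    L <- round(dur_s * fs)
    ctr <- 40 * fs
    idx <- (ctr - L %/% 2):(ctr - L %/% 2 + L - 1)
    amp[idx] <- amp[idx] + 15 * socoupling:::hann_window(L)
    x <- amp * sin(2 * pi * 13 * (0:(n - 1)) / fs)
    psg_recording(matrix(x, 1), fs, hypnogram = rep("N3", 4))
  }
  rec <- burst_rec(1.0)
  ev <- detect_spindles(rec, 1, rep(TRUE, ncol(rec$signal)), peak_freq = 13)
  hit <- which(abs(ev$peak_time - (40 * fs - 1) / fs) <= 0.1)
  expect_length(hit, 1)
  expect_true(all(ev$duration >= 0.5 & ev$duration <= 3))

  # a 0.3-s burst cannot sustain a 0.5-s run above that threshold
  rec2 <- burst_rec(0.3)
  ev2 <- detect_spindles(rec2, 1, rep(TRUE, ncol(rec2$signal)), peak_freq = 13)
  expect_false(any(abs(ev2$peak_time - (40 * fs - 1) / fs) <= 0.2))

  expect_error(detect_spindles(rec, 1, NULL, peak_freq = 20), "10, 18")
})

test_that("detected events always satisfy their duration criteria", {
  cs <- coupled_spec(fs = 128, n3_min = 4, n2_min = 2, block_min = 2)
  g <- gen_coupled_recording(cs, kappa = 2, seed = 13)
  mask <- stage_sample_mask(g$recording, c("N2", "N3"))
  recz <- znormalize(g$recording, mask)
  so <- detect_so(recz, 1, mask)
  sp <- detect_spindles(recz, 1, mask, peak_freq = 13)
  expect_true(all(so$duration >= 0.8 & so$duration <= 2))
  expect_true(all(sp$duration >= 0.5 & sp$duration <= 3))
  expect_true(all(sp$peak_time >= sp$start & sp$peak_time <= sp$end))
  expect_true(all(so$trough_time >= so$start & so$trough_time <= so$end))
  # events never overlap a rejected 5-s bin
  g$recording$artifact_mask[1, 25:30] <- TRUE
  mask2 <- stage_sample_mask(g$recording, c("N2", "N3"))
  so2 <- detect_so(znormalize(g$recording, mask2), 1, mask2)
  bad_lo <- 24 * 5; bad_hi <- 30 * 5
  expect_false(any(so2$end > bad_lo & so2$start < bad_hi))
})

test_that("epoch extraction drops edge events and z-scores rows", {
  fs <- 128
  rec <- noise_rec(rep("N3", 2), fs = fs)
  expect_warning(ep <- extract_epochs(rec, c(1.0, 30.0), 1), "edge")
  expect_equal(nrow(ep$data), 1)
  expect_equal(ncol(ep$data), 5 * fs + 1)
  expect_equal(mean(ep$data[1, ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((ep$data[1, ] - mean(ep$data[1, ]))^2)), 1,
               tolerance = 1e-9)
  ep_raw <- extract_epochs(rec, 30.0, 1, normalize = FALSE)
  expect_false(abs(sd(ep_raw$data[1, ]) - 1) < 1e-6)
})

test_that("spindle density counts stage events per 30-s epoch", {
  hyp <- c("N3", "N2", "N3")
  expect_equal(spindle_density(c(5, 10, 65, 70), hyp), 2.0)
  expect_equal(spindle_density(numeric(0), hyp), 0.0)
  expect_equal(spindle_density(c(5, 35, 65), hyp), 1.0)  # one lands in N2
  expect_error(spindle_density(c(5), rep("N2", 3)), "no N3")
})

test_that("co-occurrence rate counts spindles near SO troughs, inclusive", {
  so <- data.frame(trough_time = 11.0)
  sp <- data.frame(peak_time = c(10, 100))
  expect_equal(cooccurrence_rate(so, sp), 50)
  expect_equal(cooccurrence_rate(so[0, , drop = FALSE], sp), 0)
  expect_true(is.na(cooccurrence_rate(so, sp[0, , drop = FALSE])))
  # boundary inclusive at exactly 2.5 s
  expect_equal(cooccurrence_rate(data.frame(trough_time = 10),
                                 data.frame(peak_time = 12.5)), 100)
  # SO-denominator variant
  expect_equal(cooccurrence_rate(so, sp, denominator = "so"), 100)
})

test_that("independently placed spindles hit SO windows at the chance rate", {
  # spindles placed without regard to SOs: the hit rate must equal the time
  # coverage of the +-2.5-s SO windows (Poisson overlap logic); the
  # non-overlapping renewal placement makes the exact coverage the fair
  # expectation, with 1 - exp(-rate*5) its sparse-limit approximation
  hits <- 0; total <- 0; covered <- 0; time_total <- 0
  for (s in 1:4) {
    cs <- coupled_spec(fs = 128, n3_min = 10, n2_min = 0, p_coupled = 0,
                       uncoupled_rate_n3 = 6, uncoupled_avoid_so = FALSE,
                       so_rate_n3 = 6)
    g <- gen_coupled_recording(cs, kappa = 0, seed = 30 + s)
    tr <- g$truth
    hit <- vapply(tr$spindles$peak_time, function(t)
      any(abs(tr$so$trough_time - t) <= 2.5), TRUE)
    hits <- hits + sum(hit); total <- total + length(hit)
    dur <- ncol(g$recording$signal) / g$recording$fs
    tt <- seq(0, dur, by = 0.1)
    cov <- vapply(tt, function(t) any(abs(tr$so$trough_time - t) <= 2.5), TRUE)
    covered <- covered + sum(cov); time_total <- time_total + length(cov)
  }
  expect_gte(total, 200)
  expect_lt(abs(100 * hits / total - 100 * covered / time_total), 5)
})
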