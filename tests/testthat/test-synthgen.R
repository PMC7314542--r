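# Ground-truth generator: fractal background, SO waveform, coupled events.

test_that("fractal noise has the requested spectral slope", {
  for (beta in c(0, 2)) {
    sl <- vapply(1:20, function(s) {
      psd_slope(gen_fractal_noise(60 * 256, 256, beta, 0, seed = s), 256)
    }, 0)
    tol <- if (beta == 0) 0.1 else 0.15
    expect_lt(abs(mean(sl) + beta), tol)
  }
})

test_that("fractal noise hits the requested 1-Hz offset and is seeded", {
  x1 <- gen_fractal_noise(60 * 128, 128, 1, offset = 2, seed = 7)
  x2 <- gen_fractal_noise(60 * 128, 128, 1, offset = 2, seed = 7)
  expect_identical(x1, x2)
  # power near 1 Hz averaged over seeds (a single periodogram band holds
  # only a handful of chi-squared bins)
  p1 <- mean(vapply(1:5, function(s) {
    pg <- socoupling:::hann_periodogram(
      gen_fractal_noise(60 * 128, 128, 1, offset = 2, seed = s), 128)
    mean(pg$psd[pg$freq >= 0.8 & pg$freq <= 1.25])
  }, 0))
  expect_lt(abs(log10(p1) - 2), 0.2)
  expect_error(gen_fractal_noise(1000, 128, -0.5, 0), "beta")
})

test_that("SO waveform is a biphasic trough-then-peak cycle", {
  w <- make_so_waveform(1.333, 150, 128)
  expect_lt(abs((max(w) - min(w)) - 150), 1e-6)
  expect_equal(which.min(w), round(length(w) / 4), tolerance = 1)
  expect_lt(which.min(w), which.max(w))                 # trough precedes peak
  expect_equal(w[1], 0, tolerance = 1e-9)
  expect_equal(w[length(w)], 0, tolerance = 1e-9)
  expect_error(make_so_waveform(0.5, 100, 128), "duration")
})

test_that("von Mises phase machinery matches closed forms", {
  # degenerate concentration: all phases at mu (circular SD = 1/sqrt(kappa))
  ph <- rvonmises(200, 0, 1e5)
  expect_true(all(abs(ph) < 3 * pi / 180))
  # kappa = 0 gives uniform phases (Rayleigh null calibration)
  p_uni <- vapply(1:20, function(s) {
    set.seed(s)
    rayleigh_test(rvonmises(500, 0, 0))$p.value
  }, 0)
  expect_gte(sum(p_uni > 0.01), 19)
  # kappa = 2: resultant near I1(2)/I0(2)
  r2 <- vapply(1:10, function(s) {
    set.seed(s)
    coupling_strength(rvonmises(500, 1, 2))
  }, 0)
  expect_lt(max(abs(r2 - vonmises_resultant(2))), 0.06)
})

test_that("coupled recordings carry exact, self-consistent ground truth", {
  cs <- coupled_spec(fs = 128, n3_min = 5, n2_min = 2.5, block_min = 2.5)
  g <- gen_coupled_recording(cs, mu = 0, kappa = 2, seed = 4)
  tr <- g$truth
  dur <- ncol(g$recording$signal) / g$recording$fs
  hyp <- unclass(g$recording$hypnogram)

  # bookkeeping: events inside the recording and their stated stage
  expect_true(all(tr$so$start >= 0 & tr$so$start + tr$so$duration <= dur))
  ep_of <- floor(tr$so$trough_time / 30) + 1
  expect_true(all(hyp[ep_of] == tr$so$stage))
  ep_sp <- floor(tr$spindles$peak_time / 30) + 1
  expect_true(all(hyp[ep_sp] == tr$spindles$stage))

  # no same-type overlap (1-s minimum gap for spindles by construction)
  so_sorted <- tr$so[order(tr$so$start), ]
  expect_true(all(diff(so_sorted$start) > so_sorted$duration[-nrow(so_sorted)]))
  sp <- tr$spindles[order(tr$spindles$peak_time), ]
  lo <- sp$peak_time - sp$duration / 2; hi <- sp$peak_time + sp$duration / 2
  expect_true(all(lo[-1] >= hi[-length(hi)]))

  # ground-truth coupled phases follow the requested von Mises law
  phc <- tr$spindles$phase[tr$spindles$coupled]
  expect_gt(length(phc), 30)
  expect_lt(abs(coupling_strength(phc) - vonmises_resultant(2)), 0.12)

  # determinism
  g2 <- gen_coupled_recording(cs, mu = 0, kappa = 2, seed = 4)
  expect_identical(g$recording$signal, g2$recording$signal)
  expect_identical(g$truth$spindles, g2$truth$spindles)

  expect_error(gen_coupled_recording(coupled_spec(so_rate_n3 = 40)), "rate")
  expect_error(gen_coupled_recording(coupled_spec(spindle_freq = 22)), "10, 18")
})

test_that("phase fidelity: measured SO phase at truth peaks matches truth", {
  # noise-free recording; phases measured by the coupling module itself
  cs <- coupled_spec(fs = 128, n3_min = 5, n2_min = 0, background_sd = 0,
                     p_coupled = 1, uncoupled_rate_n3 = 0, uncoupled_rate_n2 = 0)
  g <- gen_coupled_recording(cs, mu = 33.5 * pi / 180, kappa = 3, seed = 9)
  sp <- g$truth$spindles
  ep <- suppressWarnings(
    extract_epochs(g$recording, sp$peak_time, 1, normalize = TRUE))
  measured <- so_phase_at_spindle_peak(ep)
  keep <- ep$anchors %in% sp$peak_time
  truth <- sp$phase[match(ep$anchors, sp$peak_time)]
  err <- abs(circ_dist(measured, truth)) * 180 / pi
  expect_gte(mean(err <= 10), 0.95)
})

test_that("cohorts pair timepoints, model behavior, and reproduce by seed", {
  spec <- cohort_spec(n_subjects = 3, n3_min = 2, n2_min = 0,
                      behavior_noise_sd = 0)
  coh <- gen_cohort(spec, seed = 11)
  expect_length(coh$subjects, 3)
  expect_named(coh$subjects[[1]], c("t1", "t2"))
  expect_equal(nrow(coh$behavior), 6)
  expect_true(all(coh$behavior$delayed >= 0 & coh$behavior$delayed <= 100))

  # noise-free behavior follows the linear model in delta-kappa exactly
  dk <- coh$params$kappa_t2 - coh$params$kappa_t1
  del2 <- coh$behavior$delayed[coh$behavior$timepoint == "t2"]
  expect_equal(del2, pmin(pmax(55 + 2 * dk, 0), 100), tolerance = 1e-9)

  coh2 <- gen_cohort(spec, seed = 11)
  expect_identical(coh$params, coh2$params)
  expect_identical(coh$subjects[[2]]$t1$recording$signal,
                   coh2$subjects[[2]]$t1$recording$signal)
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
})
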