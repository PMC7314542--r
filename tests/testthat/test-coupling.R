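# Event-locked coupling: phase convention, circular summaries, bootstrap,
# SO-locked time-frequency map.

make_epochs <- function(m, fs) {
  structure(list(data = m, fs = fs, anchors = seq_len(nrow(m)),
                 normalized = TRUE), class = "event_epochs")
}

test_that("phase convention: 0 at the SO positive peak, +-180 at the trough", {
  fs <- 128
  t <- seq(-2.5, 2.5, by = 1 / fs)
  at_max <- so_phase_at_spindle_peak(make_epochs(rbind(cos(2 * pi * 0.75 * t)), fs))
  expect_lt(abs(at_max) * 180 / pi, 2)
  at_min <- so_phase_at_spindle_peak(make_epochs(rbind(cos(2 * pi * 0.75 * t + pi)), fs))
  expect_lt(180 - abs(at_min) * 180 / pi, 2)
  # pure sinusoid sweep: maxima -> 0, minima -> 180 for sub-2-Hz frequencies
  for (f0 in c(0.5, 1.2)) {
    ph <- so_phase_at_spindle_peak(make_epochs(rbind(cos(2 * pi * f0 * t)), fs))
    expect_lt(abs(ph) * 180 / pi, 2)
  }
  expect_length(so_phase_at_spindle_peak(make_epochs(matrix(0, 0, 641), fs)), 0)
})

test_that("circular summaries match hand-computed values", {
  ph <- c(0, 0, pi / 2)
  expect_equal(preferred_phase(ph) * 180 / pi, 26.56505, tolerance = 1e-4)
  expect_equal(coupling_strength(ph), sqrt(5) / 3, tolerance = 1e-6)
  expect_equal(coupling_strength(c(0, pi)), 0, tolerance = 1e-12)
  expect_true(is.na(preferred_phase(c(0, pi))))
  expect_equal(preferred_phase(rep(1.1, 5)), 1.1)
  expect_equal(coupling_strength(rep(1.1, 5)), 1)
  expect_error(preferred_phase(numeric(0)))
  # rotation equivariance
  set.seed(2)
  base <- rvonmises(300, 0.4, 3)
  rot <- circ_dist(base + 1.0, 0)
  expect_equal(coupling_strength(rot), coupling_strength(base), tolerance = 1e-12)
  expect_equal(circ_dist(preferred_phase(rot), preferred_phase(base)), 1.0,
               tolerance = 1e-9)
})

test_that("pct_in_preferred implements the 45-degree window, inclusive", {
  ph8 <- seq(0, 2 * pi, length.out = 9)[-9]
  expect_equal(pct_in_preferred(ph8, 0), 12.5)
  expect_equal(pct_in_preferred(rep(0.7, 10), 0.7), 100)
  # boundary: exactly 22.5 degrees away counts
  expect_equal(pct_in_preferred(c(0, 22.5 * pi / 180), 0), 100)
  set.seed(3)
  expect_lt(abs(pct_in_preferred(runif(1e4, -pi, pi), 1.0) - 12.5), 1.5)
})

test_that("phase distance to the up-state linearizes the circular variable", {
  expect_equal(phase_distance_to_upstate(350 * pi / 180), 10, tolerance = 1e-9)
  expect_equal(phase_distance_to_upstate(-170 * pi / 180), 170, tolerance = 1e-9)
  expect_equal(phase_distance_to_upstate(0), 0)
})

test_that("bootstrap coupling matches circular expectations and its seed", {
  set.seed(10)
  uni <- runif(5000, -pi, pi)
  b1 <- bootstrap_coupling(uni, 500, 100, seed = 4)
  # E[R] under uniformity ~ sqrt(pi)/(2 sqrt(500)) = 0.0396
  expect_lt(abs(b1$mean_strength - sqrt(pi) / (2 * sqrt(500))), 0.01)
  vm <- rvonmises(5000, 0.3, 2)
  b2 <- bootstrap_coupling(vm, 500, 100, seed = 4)
  expect_lt(abs(b2$mean_strength - vonmises_resultant(2)), 0.03)
  b3 <- bootstrap_coupling(vm, 500, 100, seed = 4)
  expect_identical(b2$draws, b3$draws)
  expect_true(all(b2$draws$strength >= 0 & b2$draws$strength <= 1))
})

test_that("coupling_stats assembles the event-locked summary", {
  set.seed(11)
  ph <- rvonmises(400, 0.6, 4)
  cs <- coupling_stats(ph, channel = "Fz")
  expect_equal(cs$n_events, 400)
  expect_lt(abs(circ_dist(cs$preferred_phase, 0.6)), 0.15)
  expect_lt(abs(cs$coupling_strength - vonmises_resultant(4)), 0.05)
  expect_true(cs$pct_in_preferred > 12.5)
})

test_that("SO-locked TFR is calibrated on noise and finds injected bursts", {
  fs <- 128
  ok <- vapply(1:5, function(s) {
    set.seed(s)
    ep <- make_epochs(matrix(rnorm(25 * (5 * fs + 1)), 25), fs)
    z <- so_locked_tfr(ep, seed = 1, n_boot = 2000)
    mean(abs(z$z) <= 3)
  }, 0)
  expect_gte(min(ok), 0.985)
  expect_gte(mean(ok), 0.99)

  set.seed(6)
  m <- matrix(rnorm(25 * (5 * fs + 1)), 25)
  ctr <- (ncol(m) + 1) %/% 2
  L <- fs + 1
  burst <- 3 * sin(2 * pi * 13 * seq(-0.5, 0.5, by = 1 / fs)) *
    socoupling:::hann_window(L)
  idx <- (ctr - fs / 2):(ctr + fs / 2)
  for (i in seq_len(nrow(m))) m[i, idx] <- m[i, idx] + burst
  z <- so_locked_tfr(make_epochs(m, fs), seed = 1, n_boot = 2000)
  am <- which(z$z == max(z$z), arr.ind = TRUE)
  expect_lte(abs(z$times[am[1]]), 0.25)
  expect_lte(abs(z$freqs[am[2]] - 13), 1)

  expect_error(so_locked_tfr(make_epochs(m[1:5, ], fs)), "10 epochs")
  expect_error(so_locked_tfr(make_epochs(matrix(1, 12, 5 * fs + 1), fs),
                             n_boot = 50), "baseline")
})
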