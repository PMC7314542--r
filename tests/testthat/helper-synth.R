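# shared fixtures, built in code at test time

# small white-noise recording with a given hypnogram
noise_rec <- function(stages, fs = 128, channels = 1L, sd = 1, seed = 1) {
  set.seed(seed)
  n <- length(stages) * 30 * fs
  psg_recording(matrix(rnorm(channels * n, sd = sd), channels, n), fs,
                hypnogram = stages)
}

# least-squares log-log slope of a periodogram over a frequency band
psd_slope <- function(x, fs, lo = 1, hi = 30) {
  pg <- socoupling:::hann_periodogram(x, fs)
  k <- pg$freq >= lo & pg$freq <= hi
  unname(stats::coef(stats::lm(log10(pg$psd[k]) ~ log10(pg$freq[k])))[2])
}

# default test config: capped spectra, no bootstrap (speed)
test_config <- function(...) {
  pipeline_config(spectral_max_sec = 30, bootstrap_n_boot = 0, ...)
}
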