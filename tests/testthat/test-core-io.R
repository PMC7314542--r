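# Recording container, hypnogram/artifact I/O, stage masks, normalization.

test_that("recording construction enforces its invariants", {
  rec <- psg_recording(matrix(rnorm(2 * 512 * 60), 2), fs = 512)
  expect_equal(dim(rec$signal), c(2, 30720))          # 60 s at 512 Hz
  expect_equal(length(rec$hypnogram), 2)              # ceiling(60/30)
  expect_equal(ncol(rec$artifact_mask), 12)           # ceiling(60/5)

  m <- matrix(rnorm(1000), 1)
  expect_equal(ncol(psg_recording(m, fs = 100)$signal) / 100, 10)
  expect_error(psg_recording(matrix(numeric(0), 0, 10), fs = 100), "zero channels")
  expect_error(psg_recording(m, fs = 50), "60 Hz")
  expect_error(psg_recording(m, fs = 100, hypnogram = rep("N2", 10)),
               "hypnogram covers")
})

test_that("hypnogram files parse the token dialect, warn on unknowns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("N2,N2,N3", f)
  hyp <- load_hypnogram(f)
  expect_equal(unclass(hyp), c("N2", "N2", "N3"))
  expect_equal(length(hyp) * 30, 90)

  writeLines(c("W", "MT", "R"), f)
  expect_warning(hyp <- load_hypnogram(f), "MT")
  expect_equal(unclass(hyp), c("Wake", "Unknown", "REM"))

  writeLines(character(0), f)
  expect_error(load_hypnogram(f), "empty")

  # round-trip through the writer
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_hypnogram(c("N2", "N3", "REM"), f2)
  expect_equal(unclass(load_hypnogram(f2)), c("N2", "N3", "REM"))
})

test_that("stage masks select epochs, intersect artifacts, tile the night", {
  rec <- noise_rec(c("N2", "N3", "Wake"), fs = 128)
  m <- stage_sample_mask(rec, c("N2", "N3"))
  expect_true(all(m[1:(60 * 128)]))
  expect_false(any(m[(60 * 128 + 1):(90 * 128)]))

  # one rejected 5-s bin inside N3 knocks out exactly those samples
  rec$artifact_mask[1, 8] <- TRUE                      # 35-40 s
  m2 <- stage_sample_mask(rec, c("N2", "N3"))
  expect_false(any(m2[(35 * 128 + 1):(40 * 128)]))
  expect_true(all(m2[(40 * 128 + 1):(60 * 128)]))
  expect_equal(sum(m) - sum(m2), 5 * 128)

  # all-stage union with no artifact exclusion is all-true
  expect_true(all(stage_sample_mask(
    rec, c("Wake", "N1", "N2", "N3", "REM", "Unknown"),
    exclude_artifacts = FALSE)))

  expect_equal(sum(stage_sample_mask(noise_rec(rep("N2", 3)), "N3")), 0)
  expect_error(stage_sample_mask(rec, character(0)), "empty stage set")
})

test_that("znormalize uses population SD on the mask, applied to the trace", {
  rec <- noise_rec(rep("N2", 2), fs = 128)
  m <- rep(FALSE, ncol(rec$signal)); m[1:3] <- TRUE
  rec$signal[1, 1:3] <- c(1, 2, 3)
  rz <- znormalize(rec, m)
  expect_equal(rz$signal[1, 1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)

  # affine invariance: z(a*x + b) = z(x)
  rec2 <- rec
  rec2$signal <- rec$signal * 3.7 + 11
  expect_equal(znormalize(rec2, m)$signal, rz$signal, tolerance = 1e-9)

  # idempotence on already-normalized data
  expect_equal(znormalize(rz, m)$signal, rz$signal, tolerance = 1e-9)

  rec$signal[1, ] <- 5
  expect_error(znormalize(rec, m), "zero variance")
})

test_that("EDF round-trip preserves the signal to 16-bit quantization", {
  g <- gen_coupled_recording(
    coupled_spec(fs = 128, n3_min = 2, n2_min = 1, channels = c("C3", "C4")),
    seed = 2)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(g$recording, f)
  e <- read_edf(f)
  expect_identical(e$fs, 128)
  expect_identical(e$labels, c("C3", "C4"))
  qstep <- (max(g$recording$signal) - min(g$recording$signal)) / 65535
  expect_lt(max(abs(e$signal - g$recording$signal)), 2 * qstep)

  rec2 <- load_recording(f)
  expect_equal(dim(rec2$signal), dim(g$recording$signal))
})

test_that("package-written EDF is readable by an independent EDF reader", {
  g <- gen_coupled_recording(
    coupled_spec(fs = 128, n3_min = 1, n2_min = 1, channels = "Cz"), seed = 5)
  f <- withr::local_tempfile(fileext = ".edf")
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".txt")
  write_edf(g$recording, f)
  utils::write.csv(data.frame(x = g$recording$signal[1, 1:200]), csv,
                   row.names = FALSE)
  script <- paste(
    "import mne, numpy as np, pandas as pd",
    sprintf("raw = mne.io.read_raw_edf(%s, verbose='ERROR')", shQuote(f)),
    "x = raw.get_data()[0, :200] * 1e6",
    sprintf("ref = pd.read_csv(%s)['x'].values", shQuote(csv)),
    "print(float(np.max(np.abs(x - ref))), raw.info['sfreq'])",
    sep = "\n")
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  vals <- as.numeric(strsplit(res[length(res)], " ")[[1]])
  qstep <- diff(range(g$recording$signal)) / 65535
  expect_lt(vals[1], 2 * qstep)
  expect_identical(vals[2], 128)
})

test_that("matrix-format recordings round-trip with fs and labels", {
  rec <- noise_rec(rep("N2", 2), fs = 128, channels = 2)
  rec$channel_labels <- c("F3", "Fz")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording_matrix(rec, f)
  rec2 <- load_recording(f, format = "matrix")
  expect_equal(rec2$signal, rec$signal, tolerance = 1e-6)
  expect_identical(rec2$fs, 128)
  expect_identical(rec2$channel_labels, c("F3", "Fz"))
  expect_error(suppressWarnings(load_recording(f, format = "edf")))
})

test_that("artifact mask files round-trip", {
  m <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_artifact_mask(m, f)
  expect_identical(load_artifact_mask(f), m)
})
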