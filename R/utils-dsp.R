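# Low-level signal-processing primitives shared across modules.

# cache for FIR designs keyed by (order, cutoffs, type); fir1 is cheap but is
# called once per channel per detector, so memoise within a session
.fir_cache <- new.env(parent = emptyenv())

fir_design <- function(order, w, type) {
  key <- paste(order, paste(signif(w, 10), collapse = ","), type, sep = "|")
  b <- .fir_cache[[key]]
  if (is.null(b)) {
    b <- signal::fir1(order, w, type)
    .fir_cache[[key]] <- b
  }
  b
}

# Hamming-window FIR order for a given transition width (approx. 3.3/Df rule);
# forced even so the filter is type I (symmetric, integer group delay).
fir_order <- function(fs, trans_width) {
  n <- ceiling(3.3 * fs / trans_width)
  if (n %% 2L == 1L) n <- n + 1L
  n
}

#' Zero-phase FIR filtering
#'
#' Applies a linear-phase (symmetric) FIR filter with exact group-delay
#' compensation, which for a symmetric kernel is equivalent to zero-phase
#' filtering.  Edges are odd-reflected to suppress filter transients, and the
#' convolution runs in the frequency domain.
#'
#' @param x numeric vector.
#' @param b symmetric odd-length FIR kernel.
#' @return filtered vector, same length as `x`.
#' @keywords internal
fir_filter_zerophase <- function(x, b) {
  nb <- length(b)
  if (nb %% 2L != 1L) stop("FIR kernel must have odd length (type I)")
  half <- (nb - 1L) %/% 2L
  n <- length(x)
  npad <- min(n - 1L, nb)
  left <- 2 * x[1L] - x[(npad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(left, x, right)
  nfft <- stats::nextn(length(xp) + nb - 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  B <- stats::fft(c(b, rep(0, nfft - nb)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
  y[(npad + half + 1L):(npad + half + n)]
}

# Row-wise zero-phase FIR filtering of a matrix (rows = epochs), batched
# through mvfft; same padding and alignment as fir_filter_zerophase.
fir_filter_zerophase_rows <- function(m, b) {
  nb <- length(b)
  half <- (nb - 1L) %/% 2L
  n <- ncol(m)
  npad <- min(n - 1L, nb)
  xt <- t(m)                                   # samples x epochs
  left <- 2 * xt[rep(1L, npad), , drop = FALSE] - xt[(npad + 1L):2L, , drop = FALSE]
  right <- 2 * xt[rep(n, npad), , drop = FALSE] - xt[(n - 1L):(n - npad), , drop = FALSE]
  xp <- rbind(left, xt, right)
  nfft <- stats::nextn(nrow(xp) + nb - 1L, c(2L, 3L, 5L))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - nrow(xp), ncol(xp))))
  B <- stats::fft(c(b, rep(0, nfft - nb)))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  t(y[(npad + half + 1L):(npad + half + n), , drop = FALSE])
}

lowpass_filter <- function(x, fs, hi, trans_width = 0.5) {
  b <- fir_design(fir_order(fs, trans_width), hi / (fs / 2), "low")
  fir_filter_zerophase(x, b)
}

highpass_filter <- function(x, fs, lo, trans_width = 0.1) {
  b <- fir_design(fir_order(fs, trans_width), lo / (fs / 2), "high")
  fir_filter_zerophase(x, b)
}

bandpass_filter <- function(x, fs, lo, hi, trans_width = 0.5) {
  b <- fir_design(fir_order(fs, trans_width), c(lo, hi) / (fs / 2), "pass")
  fir_filter_zerophase(x, b)
}

#' Analytic signal via the frequency domain
#'
#' @param x real vector.
#' @return complex vector whose modulus is the instantaneous amplitude and
#'   whose argument is the instantaneous phase.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Centered moving average with shrinking windows at the edges (no NA padding).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fourier-domain resampling to a target length
#'
#' Band-limited resampling of `x` onto `m` points spanning the same interval,
#' by truncating or zero-padding the discrete spectrum.  Used by the IRASA
#' decomposition, where a segment resampled to length `round(n*h)` and read at
#' the nominal rate is the "stretched by h" segment.
#'
#' @param x numeric vector.
#' @param m target length.
#' @return numeric vector of length `m`.
#' @keywords internal
resample_fft <- function(x, m) {
  n <- length(x)
  m <- as.integer(m)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  k <- min(n, m)
  nh <- (k + 1L) %/% 2L             # positive-frequency bins kept, incl. DC
  Y[1:nh] <- X[1:nh]
  if (k > 1L) {
    nneg <- k - nh                  # negative-frequency bins kept
    if (nneg > 0L) Y[(m - nneg + 1L):m] <- X[(n - nneg + 1L):n]
    if (k %% 2L == 0L) {            # split/assign the Nyquist bin
      if (m < n) {
        Y[nh + 1L] <- Re(X[nh + 1L])
      } else {
        Y[nh + 1L] <- X[nh + 1L] / 2
        Y[m - nh + 1L] <- Conj(X[nh + 1L]) / 2
      }
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# One-sided Hann-tapered periodogram (power spectral density, unit^2/Hz).
# Returns frequencies above DC up to (not including) Nyquist.
hann_periodogram <- function(seg, fs) {
  n <- length(seg)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  s <- (seg - mean(seg)) * w
  p <- Mod(stats::fft(s))^2 / (fs * sum(w^2))
  kmax <- floor((n - 1) / 2)
  idx <- 2:(kmax + 1L)
  list(freq = (idx - 1L) * fs / n, psd = 2 * p[idx])
}

# Sum of one-sided Hann periodograms over windows of length L starting at
# `starts` within `x`, batched through mvfft.  Same bins as
# hann_periodogram (k = 1 .. min(floor((L-1)/2), k_keep)).
hann_periodogram_sum <- function(x, starts, L, fs, k_keep = Inf) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  segs <- matrix(x[outer(0:(L - 1L), starts, "+")], nrow = L)
  segs <- sweep(segs, 2, colMeans(segs), "-") * w
  kmax <- min(floor((L - 1) / 2), k_keep)
  P <- stats::mvfft(segs)[2:(kmax + 1L), , drop = FALSE]
  2 * rowSums(Mod(P)^2) / (fs * sum(w^2))
}

# 5-smooth (2^a 3^b 5^c) integer closest to m: mixed-radix FFT lengths
.smooth_cache <- new.env(parent = emptyenv())
five_smooth_near <- function(m) {
  tab <- .smooth_cache$tab
  if (is.null(tab)) {
    p2 <- 2^(0:24); p3 <- 3^(0:15); p5 <- 5^(0:10)
    tab <- sort(as.numeric(outer(outer(p2, p3), p5)))
    tab <- tab[tab <= 2^24]
    .smooth_cache$tab <- tab
  }
  tab[which.min(abs(tab - m))]
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # convention: interval (-pi, pi]
  out[out == -pi] <- pi
  out
}
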