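# Circular statistics used by the coupling and stats modules.
# Conventions follow the common EEG usage: phases in radians, wrapped to
# (-pi, pi], 0 = slow-oscillation positive peak ("up-state"), +-pi = trough.

#' Circular mean direction (preferred phase)
#'
#' Direction of the mean unit vector of a sample of phases.
#'
#' @param phases numeric vector of phase angles in radians.
#' @return mean direction in radians, wrapped to (-pi, pi]; `NA` if the
#'   resultant length is exactly zero (direction undefined).
#' @export
#' @examples
#' preferred_phase(c(0, 0, pi / 2)) * 180 / pi # 26.57 degrees
preferred_phase <- function(phases) {
  if (length(phases) == 0L) stop("preferred_phase: no phases supplied")
  z <- mean(exp(1i * phases))
  if (Mod(z) < .Machine$double.eps^0.5) return(NA_real_)
  wrap_phase(Arg(z))
}

#' Coupling strength (resultant vector length / phase-locking value)
#'
#' Length of the mean unit vector of a sample of phases; 0 means no phase
#' preference, 1 perfect locking.  Reported without small-sample bias
#' correction (the conventional resultant-length estimator, which has a
#' positive bias of about sqrt(pi)/(2*sqrt(n)) under uniformity).
#'
#' @param phases numeric vector of phase angles in radians.
#' @return resultant length in \[0, 1\].
#' @export
coupling_strength <- function(phases) {
  if (length(phases) == 0L) stop("coupling_strength: no phases supplied")
  Mod(mean(exp(1i * phases)))
}

#' Pairwise circular distance
#'
#' Signed angular difference a - b wrapped to (-pi, pi].
#' @param a,b phase angles in radians (recycled).
#' @return wrapped differences.
#' @export
circ_dist <- function(a, b) wrap_phase(a - b)

# circular standard deviation (angular deviation, Mardia): sqrt(-2 log R)
circ_sd <- function(phases) {
  r <- coupling_strength(phases)
  sqrt(-2 * log(max(r, .Machine$double.xmin)))
}

#' von Mises mean resultant length
#'
#' Closed form I1(kappa)/I0(kappa): the population coupling strength of
#' phases drawn from a von Mises distribution with concentration `kappa`.
#' @param kappa concentration parameter (>= 0).
#' @export
vonmises_resultant <- function(kappa) {
  ifelse(kappa == 0, 0, besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; reduces to uniform angles at
#' kappa = 0.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return phases in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_phase(mu + out)
}

#' Rayleigh test for circular uniformity
#'
#' @param phases phase angles in radians.
#' @return list with the resultant length `r`, test statistic `z = n r^2` and
#'   approximate p-value (Zar's correction).
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  r <- coupling_strength(phases)
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  list(r = r, statistic = z, p.value = min(1, p))
}
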