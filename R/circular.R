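# Circular statistics used throughout the lever-frame and drift analyses.
# Angles at the API boundary are in degrees; radians are used internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [-180, 180)
#'
#' @param x Angles in degrees.
#' @return Angles wrapped to the half-open interval \[-180, 180).
#' @export
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Circular mean direction
#'
#' Mean direction of a set of angles, optionally weighted (e.g. by firing
#' rate when summarizing a directional tuning curve).
#'
#' @param x Angles in degrees.
#' @param w Optional non-negative weights, recycled against `x`.
#' @return Mean direction in degrees in \[-180, 180), or `NA` if the
#'   resultant length is (numerically) zero.
#' @export
circular_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- is.finite(x) & is.finite(w)
  x <- x[ok]; w <- w[ok]
  if (!length(x) || sum(w) <= 0) return(NA_real_)
  a <- deg2rad(x)
  s <- sum(w * sin(a)); c <- sum(w * cos(a))
  if (sqrt(s^2 + c^2) / sum(w) < 1e-12) return(NA_real_)
  wrap180(rad2deg(atan2(s, c)))
}

#' Mean vector length
#'
#' Resultant length of unit vectors at the given angles; 1 means perfectly
#' concentrated directions, 0 a uniform distribution. With weights this is
#' the rate-weighted resultant used for directional tuning curves.
#'
#' @param x Angles in degrees.
#' @param w Optional non-negative weights.
#' @return Mean vector length in \[0, 1\].
#' @export
mean_vector_length <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- is.finite(x) & is.finite(w)
  x <- x[ok]; w <- w[ok]
  if (!length(x) || sum(w) <= 0) return(NA_real_)
  a <- deg2rad(x)
  sqrt(sum(w * sin(a))^2 + sum(w * cos(a))^2) / sum(w)
}

#' Circular-circular correlation (Fisher-Lee)
#'
#' Fisher-Lee sine-of-pairwise-differences estimator of association between
#' two circular variables, used to relate per-trial field drift to homing
#' direction.
#'
#' @param a,b Paired angles in degrees.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
circular_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- deg2rad(a[ok]); b <- deg2rad(b[ok])
  n <- length(a)
  if (n < 3) stop("need at least 3 paired angles")
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  up <- upper.tri(sa)
  num <- sum(sa[up] * sb[up])
  den <- sqrt(sum(sa[up]^2) * sum(sb[up]^2))
  if (den == 0) stop("degenerate (constant) circular variable")
  num / den
}

#' Rayleigh test of circular uniformity
#'
#' @param x Angles in degrees.
#' @return List with the resultant length `r`, statistic `z = n r^2`, and
#'   approximate p-value.
#' @export
rayleigh_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 angles")
  r <- mean_vector_length(x)
  z <- n * r^2
  # standard large-sample approximation with finite-n correction
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (r * n)^2)) - (1 + 2 * n))
  list(r = r, z = z, p.value = min(max(p, 0), 1), n = n)
}

# Von Mises sampler (Best & Fisher 1979 rejection method); mu in degrees,
# kappa >= 0. Used by the synthetic generator; depends only on stats::runif
# so that set.seed() gives reproducible sessions.
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap180(mu + rad2deg(out))
}
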