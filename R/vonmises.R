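# von Mises sampling by the Best-Fisher (1979) wrapping rejection
# algorithm. kappa = 0 degenerates to the uniform distribution on the
# circle. Implemented here because the generator needs it and no installed
# package provides circular distributions.

#' Sample from a von Mises distribution
#'
#' The von Mises distribution is the circular analogue of the normal
#' distribution, with mean direction `mu` and concentration `kappa`
#' (larger kappa = more concentrated; `kappa = 0` is the uniform circular
#' distribution). Uses the Best-Fisher rejection sampler. Draws from R's
#' global random number stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, >= 0.
#' @return Numeric vector of `n` angles in `[0, 2*pi)`.
#' @export
#' @examples
#' set.seed(1)
#' th <- rvonmises(500, mu = pi / 4, kappa = 20)
#' circular_sd(th) # close to 1/sqrt(20)
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            kappa >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))

  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)

  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    acc <- theta[keep]
    k <- length(acc)
    if (k > 0L) {
      out[(got + 1L):(got + k)] <- acc
      got <- got + k
    }
  }
  wrap_angle(mu + out, 2 * pi)
}

#' Expected circular standard deviation of a von Mises population
#'
#' Closed form from the Bessel-function ratio: the population mean
#' resultant length is `A(kappa) = I1(kappa) / I0(kappa)`, so the
#' population circular standard deviation is `sqrt(-2 ln A(kappa))`.
#' Useful as an analytic reference when validating dispersion estimates
#' on simulated fields.
#'
#' @param kappa Concentration parameter, > 0.
#' @return Population circular standard deviation in radians.
#' @export
vonmises_circular_sd <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa > 0))
  # exponentially scaled Bessel ratio for numerical stability at large kappa
  A <- besselI(kappa, 1, expon.scaled = TRUE) /
       besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(A))
}
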