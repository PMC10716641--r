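#' @useDynLib sonarCEE, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim optimHess rgamma rpois runif rnorm qnorm pnorm
#'   pchisq setNames aggregate complete.cases cov sd var cor
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Wrap angles into (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' Circular mean of angles
#'
#' @param x angles in radians.
#' @return mean direction in (-pi, pi]; `NA` if the resultant length is 0.
#' @export
circular_mean <- function(x) {
  s <- sum(sin(x)); c <- sum(cos(x))
  if (s == 0 && c == 0) return(NA_real_)
  atan2(s, c)
}

#' von Mises log density
#'
#' kappa = 0 gives the circular uniform density 1/(2*pi). The Bessel term is
#' evaluated with the exponentially scaled besselI for stability at large kappa.
#'
#' @param x angle in radians.
#' @param mu mean direction.
#' @param kappa concentration (>= 0).
#' @return log density.
#' @export
dvonmises <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; kappa = 0 falls back to the circular uniform.
#'
#' @param n number of draws.
#' @param mu mean direction.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- wrap_angle(sign(u[3] - 0.5) * acos(f) + mu)
        break
      }
    }
  }
  out
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Deterministic integer mixing so every pipeline stage gets an independent,
#' reproducible stream; results stay below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage stage label (character) or integer offset.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  off <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.integer(stage)
  as.integer((as.double(seed) * 2654435.0 + off * 97.0 + 12345.0) %% 2147483647)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
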