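#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `(-pi, pi]`.
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
#' @export
wrap_angle <- function(theta) {
  w <- theta %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used by the synthetic generator to
#' model head-bow phase noise; `kappa = 0` gives the circular uniform.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0); larger is less dispersed.
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(length(n) == 1L, n >= 0, kappa >= 0, is.finite(kappa))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Mean resultant length of a von Mises distribution
#'
#' The population vector length `I1(kappa)/I0(kappa)`; the expected VL of
#' phase samples whose noise is von Mises with concentration `kappa`.
#'
#' @param kappa concentration parameter (>= 0).
#' @return numeric in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  ifelse(kappa <= 0, 0, besselI(kappa, 1) / besselI(kappa, 0))
}
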