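#' Convert a mean/sd pair to gamma shape and scale
#'
#' The movement model specifies step-length distributions by their mean and
#' standard deviation; `rgamma()` wants shape and scale. Moment matching gives
#' `shape = (mean/sd)^2` and `scale = sd^2/mean`.
#'
#' @param mean,sd Desired mean and standard deviation (> 0).
#' @return A named list with elements `shape` and `scale`.
#' @examples
#' gamma_params(7, 5) # shape 1.96, scale 25/7
#' @export
gamma_params <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    abort("`mean` must be a single positive number.")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    abort("`sd` must be a single positive number.")
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Draw from a Von Mises distribution
#'
#' Circular analogue of the normal distribution, used for step directions.
#' Implements the Best-Fisher (1979) wrapped-Cauchy rejection sampler; draws
#' are location-shifted by `mu` and wrapped to `[-pi, pi)`. `kappa = 0` is the
#' uniform distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction(s), radians; recycled to length `n`.
#' @param kappa Concentration parameter (single value, >= 0).
#' @return Numeric vector of `n` angles in `[-pi, pi)`.
#' @examples
#' set.seed(1)
#' mean(cos(rvonmises(1e4, 0, 10))) # close to 1: tightly concentrated
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (!is_count(n, min = 0L)) abort("`n` must be a single non-negative integer.")
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    abort("`kappa` must be a single number >= 0.")
  }
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  mu <- rep_len(mu, n)
  if (kappa < 1e-10) {
    return(wrap_angle(runif(n, -pi, pi)))
  }

  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)

  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    m <- length(need)
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out[need[accept]] <- sign(u3[accept] - 0.5) * acos(pmin(pmax(f[accept], -1), 1))
    need <- need[!accept]
  }
  wrap_angle(out + mu)
}

#' Sample step lengths from a configuration's step-length distribution
#'
#' Draws from the gamma distribution whose mean and sd are `cfg$step_mean` and
#' `cfg$step_sd` — the distribution actually used for every agent movement
#' step in [simulate_tracks()].
#'
#' @param cfg A [sim_config()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative step lengths.
#' @export
sample_step_lengths <- function(cfg, n) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_count(n, min = 0L)) abort("`n` must be a single non-negative integer.")
  p <- gamma_params(cfg$step_mean, cfg$step_sd)
  rgamma(n, shape = p$shape, scale = p$scale)
}
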