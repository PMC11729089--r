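# Extrinsic drive generators: homogeneous Poisson trains, sinusoidally
# rate-modulated (theta) trains, jittered rhythmic event times, and
# Ornstein-Uhlenbeck background conductances.

#' Homogeneous Poisson spike train
#'
#' @param rate_hz firing rate, Hz (>= 0).
#' @param duration_ms train length, ms.
#' @param seed integer seed (optional; uses current RNG state when NULL).
#' @return strictly increasing spike times in (0, duration_ms), ms.
#' @export
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (rate_hz < 0) stopf("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (rate_hz == 0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}

#' Theta-modulated spike train (Bernoulli thinning of a sinusoidal rate)
#'
#' Instantaneous rate r(t) = A*sin(2*pi*f*t + phi) + off with
#' A = off/(1/d - 1), clamped at 0; a spike is emitted in each bin of width
#' dt when a uniform draw is <= r(t)*dt.
#'
#' @param f modulation frequency, Hz.
#' @param off offset (mean unmodulated) rate, Hz.
#' @param depth modulation depth d in (0, 1).
#' @param phase phase offset phi, rad.
#' @param duration_ms,dt_ms train length and bin width, ms.
#' @param seed integer seed (optional).
#' @return spike times, ms.
#' @export
theta_modulated_train <- function(f = 8, off = 2, depth = 0.7, phase = 0,
                                  duration_ms = 1000, dt_ms = 0.1, seed = NULL) {
  stopifnot(depth > 0, depth < 1, dt_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  A <- off / (1 / depth - 1)
  t <- seq(0, duration_ms - dt_ms, by = dt_ms)
  r <- A * sin(2 * pi * f * t / 1000 + phase) + off   # Hz
  r <- pmax(r, 0)
  p <- r * dt_ms / 1000
  if (any(p >= 1)) stopf("rate * dt >= 1: decrease dt")
  t[stats::runif(length(t)) <= p]
}

#' Amplitude of the sinusoidal rate modulation
#' @param off offset rate, Hz; @param depth modulation depth in (0,1).
#' @export
theta_amplitude <- function(off, depth) off / (1 / depth - 1)

#' Jittered rhythmic event times
#'
#' Event j occurs at j*T plus an independent Gaussian displacement with SD
#' \code{sigma_ms}; times are re-sorted if displacements reorder them.
#'
#' @param period_ms base period T, ms.
#' @param sigma_ms jitter SD, ms (>= 0).
#' @param n_events number of events (>= 1).
#' @param seed integer seed (optional).
#' @export
jittered_rhythmic_times <- function(period_ms, sigma_ms, n_events, seed = NULL) {
  stopifnot(n_events >= 1, sigma_ms >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_events)) * period_ms + stats::rnorm(n_events, 0, sigma_ms)
  sort(t)
}

#' Ornstein-Uhlenbeck conductance trace (reference implementation)
#'
#' Exact discretisation of the stationary OU process:
#' g[k+1] = mean + (g[k]-mean)*e + sd*sqrt(1-e^2)*N(0,1), e = exp(-dt/tau).
#' The integration core uses the identical recursion; negative excursions are
#' floored at 0 at the point of use (conductances cannot be negative).
#'
#' @param mean,sd stationary mean and SD of the conductance, uS.
#' @param tau correlation time constant, ms.
#' @param duration_ms,dt_ms trace length and step, ms.
#' @param seed integer seed (optional).
#' @return numeric vector of conductances at dt resolution.
#' @export
ou_conductance <- function(mean, sd, tau, duration_ms, dt_ms = 0.1, seed = NULL) {
  stopifnot(sd >= 0, tau > 0, dt_ms < tau)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_ms / dt_ms)
  e <- exp(-dt_ms / tau)
  s <- sd * sqrt(1 - e^2)
  g <- numeric(n)
  g[1] <- mean + sd * stats::rnorm(1)
  if (n > 1) {
    z <- stats::rnorm(n - 1)
    for (k in 2:n) g[k] <- mean + (g[k - 1] - mean) * e + s * z[k - 1]
  }
  g
}

# The two VP/SI afferent regimes.  Non-theta cases: independent 2 Hz Poisson.
# Theta cases: the common 8 Hz sinusoidal rate (Bernoulli-thinned per
# afferent) so that afferents share the population rhythm but spike
# independently.
vpsi_regime <- function(case_id) {
  if (case_id %in% c(2, 3, 4)) "theta" else "poisson"
}
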