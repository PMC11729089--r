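# Spectral and phase analytics: Welch power spectral density, peak theta
# power, zero-phase Butterworth band-pass, Hilbert-phase spike entrainment,
# circular statistics, and cross-correlogram lags.

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, mean-detrended, 50%-overlapping
#' segments; one-sided density normalised so that the integral of the PSD
#' approximates the signal variance.
#'
#' @param x signal; @param fs sampling rate, Hz.
#' @param window_sec segment length, s; @param overlap fractional overlap.
#' @return list with \code{freq} (Hz), \code{power} (x^2/Hz) and
#'   \code{df} (frequency resolution).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (length(x) < 2 * nw * (1 - overlap) + nw * overlap)
    if (length(x) < nw) stopf("trace shorter than one Welch window")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))   # Hann
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  if (!length(starts)) stopf("trace shorter than one Welch window")
  u <- sum(w^2)
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nw %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / length(starts) / (fs * u)
  p[c(-1, -length(p))] <- 2 * p[c(-1, -length(p))]       # one-sided
  freq <- (seq_along(p) - 1) * fs / nw
  list(freq = freq, power = p, df = fs / nw)
}

#' Peak power in a frequency band
#'
#' @param psd a \code{\link{welch_psd}} result.
#' @param band search band (low, high), Hz.
#' @return list(freq, power) of the maximum within the band.
#' @export
peak_power <- function(psd, band = c(4, 12)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stopf("band outside the spectrum")
  i <- which(sel)[which.max(psd$power[sel])]
  list(freq = psd$freq[i], power = psd$power[i])
}

#' Theta peak prominence over the broadband floor
#'
#' Ratio of the peak theta-band power to the mean power in the floor band
#' (default 12-20 Hz); a rhythm-free spectrum gives a ratio near 1.
#' @export
theta_prominence <- function(psd, theta_band = c(4, 12), floor_band = c(12, 20)) {
  pk <- peak_power(psd, theta_band)
  fl <- psd$freq > floor_band[1] & psd$freq <= floor_band[2]
  pk$power / mean(psd$power[fl])
}

#' Zero-phase theta band-pass filter
#'
#' 2-pole Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), giving zero net phase shift.
#'
#' @param x signal; @param fs sampling rate, Hz.
#' @param band pass band (low, high), Hz.
#' @export
bandpass_theta <- function(x, fs, band = c(4, 12)) {
  if (fs <= 2 * band[2]) stopf("sampling rate incompatible with band edges")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic-signal (Hilbert) phase
#'
#' FFT-based analytic signal; phase convention: 90 deg at the oscillation
#' peak, 270 deg at the trough (sine-referenced).
#'
#' @param x band-passed signal.
#' @return list with \code{phase_deg} in [0, 360) and \code{amplitude}.
#' @export
hilbert_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1
    hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1; hmul[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * hmul, inverse = TRUE) / n
  ph <- (Arg(z) * 180 / pi + 90) %% 360
  list(phase_deg = ph, amplitude = Mod(z))
}

#' Circular mean and resultant length
#'
#' @param deg angles in degrees.
#' @return list(mean_deg, resultant) with mean in [0, 360).
#' @export
circ_mean <- function(deg) {
  if (!length(deg)) return(list(mean_deg = NA_real_, resultant = NA_real_))
  th <- deg * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  list(mean_deg = (atan2(S, C) * 180 / pi) %% 360,
       resultant = sqrt(C^2 + S^2))
}

#' Rayleigh test of circular uniformity
#' @param deg angles in degrees.
#' @return list(R, p) with the resultant length and the Rayleigh p value.
#' @export
rayleigh_test <- function(deg) {
  n <- length(deg)
  R <- circ_mean(deg)$resultant
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(R = R, p = max(min(p, 1), 0))
}

#' Spike-phase entrainment histogram
#'
#' Assigns to each spike the analytic-signal phase of the filtered LFP at
#' its time (linear interpolation between samples) and histograms the phases
#' per group.
#'
#' @param spikes data frame with \code{time_ms} and \code{cell_type} (or a
#'   numeric vector of spike times for a single group).
#' @param theta_phase_deg per-sample phase of the band-passed LFP.
#' @param t_ms sample times of the LFP trace, ms.
#' @param n_bins histogram bins over [0, 360).
#' @return list per group: \code{prob} (per-bin firing probability, sums to
#'   1), \code{bin_centers_deg}, \code{preferred_deg}, \code{resultant},
#'   \code{n}; groups with no spikes are flagged \code{empty}.
#' @export
phase_entrainment <- function(spikes, theta_phase_deg, t_ms, n_bins = 24) {
  if (is.numeric(spikes)) spikes <- data.frame(time_ms = spikes, cell_type = "all")
  edges <- seq(0, 360, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  # interpolate phase circularly via its unit vector
  cph <- cos(theta_phase_deg * pi / 180); sph <- sin(theta_phase_deg * pi / 180)
  out <- list()
  for (g in unique(spikes$cell_type)) {
    ts <- spikes$time_ms[spikes$cell_type == g]
    ts <- ts[ts >= min(t_ms) & ts <= max(t_ms)]
    if (!length(ts)) {
      out[[g]] <- list(empty = TRUE, preferred_deg = NA_real_,
                       resultant = NA_real_, n = 0L)
      next
    }
    c_i <- approx(t_ms, cph, ts)$y
    s_i <- approx(t_ms, sph, ts)$y
    ph <- (atan2(s_i, c_i) * 180 / pi) %% 360
    h <- tabulate(findInterval(ph, edges, rightmost.closed = TRUE),
                  nbins = n_bins)
    cm <- circ_mean(ph)
    out[[g]] <- list(empty = FALSE, prob = h / sum(h),
                     bin_centers_deg = centers,
                     preferred_deg = cm$mean_deg, resultant = cm$resultant,
                     n = length(ph))
  }
  out
}

#' Cross-correlogram of two pooled spike trains
#'
#' Histogram of target-minus-reference spike-time differences within
#' \code{max_lag_ms}; the peak lag is the bin centre of the smoothed maximum
#' (3-bin moving average).  A positive peak lag means the reference group
#' leads.
#'
#' @param ref,target spike time vectors, ms.
#' @param max_lag_ms window half-width; @param bin_ms bin width.
#' @return list(lags_ms, counts, peak_lag_ms).
#' @export
cross_correlogram <- function(ref, target, max_lag_ms = 20, bin_ms = 0.5) {
  if (!length(ref) || !length(target)) stopf("both groups must be non-empty")
  ref <- sort(ref); target <- sort(target)
  edges <- seq(-max_lag_ms - bin_ms / 2, max_lag_ms + bin_ms / 2, by = bin_ms)
  counts <- numeric(length(edges) - 1)
  j0 <- 1
  for (r in ref) {
    while (j0 <= length(target) && target[j0] < r - max_lag_ms - bin_ms) j0 <- j0 + 1
    j <- j0
    while (j <= length(target) && target[j] <= r + max_lag_ms + bin_ms) {
      d <- target[j] - r
      k <- findInterval(d, edges)
      if (k >= 1 && k <= length(counts)) counts[k] <- counts[k] + 1
      j <- j + 1
    }
  }
  lags <- (edges[-1] + edges[-length(edges)]) / 2
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  list(lags_ms = lags, counts = counts,
       peak_lag_ms = lags[which.max(sm)])
}
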