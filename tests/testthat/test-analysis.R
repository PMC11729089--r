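# Spectral and phase analytics.

fs <- 2000

test_that("Welch PSD finds sinusoid peaks at their frequencies", {
  t <- seq(0, 20, by = 1 / fs)[-1]
  x <- sin(2 * pi * 8 * t)
  psd <- welch_psd(x, fs, window_sec = 2)
  expect_equal(peak_power(psd, c(4, 12))$freq, 8, tolerance = psd$df / 2 / 8)
  x2 <- x + 0.5 * sin(2 * pi * 40 * t)
  psd2 <- welch_psd(x2, fs, window_sec = 2)
  expect_equal(peak_power(psd2, c(4, 12))$freq, 8, tolerance = psd$df / 2 / 8)
  expect_equal(peak_power(psd2, c(30, 50))$freq, 40, tolerance = psd$df / 2 / 40)
  expect_error(welch_psd(x[1:100], fs, window_sec = 2), "shorter")
})

test_that("white-noise spectrum is flat (log-log slope ~ 0)", {
  set.seed(31)
  slopes <- replicate(30, {
    psd <- welch_psd(rnorm(fs * 4), fs, window_sec = 0.5)
    sel <- psd$freq > 2 & psd$freq < 900
    unname(stats::coef(stats::lm(log(psd$power[sel]) ~ log(psd$freq[sel])))[2])
  })
  ci <- mean(slopes) + c(-3, 3) * sd(slopes) / sqrt(length(slopes))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("integrated PSD approximates the signal variance", {
  set.seed(32)
  x <- as.numeric(stats::filter(rnorm(fs * 30), rep(0.2, 5), sides = 1))
  x <- x[!is.na(x)]
  psd <- welch_psd(x, fs, window_sec = 1)
  expect_equal(sum(psd$power) * psd$df, var(x), tolerance = 0.05)
})

test_that("theta band-pass passes 8 Hz, rejects 50 Hz, and adds no phase shift", {
  t <- seq(0, 10, by = 1 / fs)[-1]
  x8 <- sin(2 * pi * 8 * t)
  y8 <- bandpass_theta(x8, fs)
  core <- seq(fs, length(t) - fs)    # ignore filter edges
  expect_gt(sd(y8[core]) / sd(x8[core]), 0.9)
  y50 <- bandpass_theta(sin(2 * pi * 50 * t), fs)
  # two-pass (squared) 2-pole Butterworth magnitude response at 50 Hz,
  # evaluated directly from the transfer-function coefficients
  bf <- signal::butter(2, c(4, 12) / (fs / 2), "pass")
  zi <- exp(-1i * 2 * pi * 50 / fs * (seq_along(bf$b) - 1))
  H <- Mod(sum(bf$b * zi) / sum(bf$a * zi))^2
  expect_lt(sd(y50[core]) / sd(x8[core]), 0.1)
  expect_equal(sd(y50[core]) / sd(x8[core]), H, tolerance = 0.2)
  # zero net phase: 8 Hz phase shift below one sample (projection method)
  ph_of <- function(x) atan2(sum(x[core] * cos(2 * pi * 8 * t[core])),
                             sum(x[core] * sin(2 * pi * 8 * t[core])))
  shift_samples <- abs(ph_of(y8) - ph_of(x8)) / (2 * pi * 8) * fs
  expect_lte(shift_samples, 1)
})

test_that("analytic-signal phase uses the peak=90, trough=270 convention", {
  t <- seq(0, 5, by = 1 / fs)[-1]
  x <- sin(2 * pi * 8 * t)
  hp <- hilbert_phase(x)
  pk <- which.max(x[1000:3000]) + 999
  tr <- which.min(x[1000:3000]) + 999
  expect_equal(hp$phase_deg[pk], 90, tolerance = 1)
  expect_equal(hp$phase_deg[tr], 270, tolerance = 1)
})

test_that("phase entrainment recovers planted spike phases", {
  t_ms <- seq(0.5, 10000, by = 0.5)
  lfp <- sin(2 * pi * 8 * t_ms / 1000)
  hp <- hilbert_phase(bandpass_theta(lfp, fs))
  period <- 125
  troughs <- seq(3 * period / 4, 9000, by = period)   # sine troughs
  out <- phase_entrainment(troughs, hp$phase_deg, t_ms)
  expect_equal(out$all$preferred_deg, 270, tolerance = 3)
  expect_gt(out$all$resultant, 0.95)
  # spikes 45 degrees after the trough
  late <- troughs + period / 8
  out2 <- phase_entrainment(late, hp$phase_deg, t_ms)
  expect_equal(out2$all$preferred_deg, 315, tolerance = 5)
  # uniform spikes: Rayleigh test not significant
  set.seed(33)
  unif <- runif(300, 100, 9900)
  out3 <- phase_entrainment(unif, hp$phase_deg, t_ms)
  ph <- (atan2(sin(2 * pi * 8 * unif / 1000 - pi / 2),
               cos(2 * pi * 8 * unif / 1000 - pi / 2)))
  expect_gt(rayleigh_test((360 * 8 * unif / 1000) %% 360)$p, 0.01)
  expect_lt(out3$all$resultant, 0.15)
  # empty group flagged, not NaN-propagated
  sp <- data.frame(time_ms = troughs, cell_type = "PN_A")
  sp2 <- rbind(sp, data.frame(time_ms = numeric(0), cell_type = character(0)))
  out4 <- phase_entrainment(sp, hp$phase_deg, t_ms)
  expect_false(out4$PN_A$empty)
})

test_that("end-to-end entrainment recovers phase within 10 degrees at lock >= 0.3", {
  set.seed(34)
  t_ms <- seq(0.5, 20000, by = 0.5)
  lfp <- sin(2 * pi * 8 * t_ms / 1000) + 0.5 * rnorm(length(t_ms))
  hp <- hilbert_phase(bandpass_theta(lfp, fs))
  # wrapped-normal spikes at 200 deg preferred phase, moderate lock; for
  # x = sin(2 pi f t) the phase convention gives phase(t) = 360 f t mod 360
  n <- 2000
  ph_target <- (200 + 50 * rnorm(n)) %% 360
  cyc <- sample(10:150, n, TRUE)
  spike_t <- cyc * 125 + ph_target / 360 * 125
  out <- phase_entrainment(spike_t, hp$phase_deg, t_ms)
  expect_gt(out$all$resultant, 0.3)
  d <- abs(((out$all$preferred_deg - 200 + 180) %% 360) - 180)
  expect_lt(d, 10)
})

test_that("cross-correlogram peak lag recovers planted shifts", {
  set.seed(35)
  ref <- sort(runif(2000, 0, 60000))
  cc0 <- cross_correlogram(ref, ref)
  expect_equal(cc0$peak_lag_ms, 0, tolerance = 1e-9)
  cc <- cross_correlogram(ref, ref + 4.5)
  expect_equal(cc$peak_lag_ms, 4.5, tolerance = 0.5)
  # unbiased over the +-20 ms range (|bias| < bin width)
  for (shift in c(-15, -5, 10, 18)) {
    cc <- cross_correlogram(ref, ref + shift, max_lag_ms = 20, bin_ms = 0.5)
    expect_lt(abs(cc$peak_lag_ms - shift), 0.5 + 1e-9)
  }
  # independent Poisson trains: flat correlogram
  tgt <- sort(runif(2000, 0, 60000))
  cc2 <- cross_correlogram(ref, tgt)
  m <- mean(cc2$counts)
  expect_lt(max(cc2$counts), m + 4 * sqrt(m))
  expect_error(cross_correlogram(numeric(0), ref), "non-empty")
})
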