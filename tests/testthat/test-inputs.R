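# Extrinsic drive generators.

test_that("homogeneous Poisson trains have Poisson count moments and CV(ISI) ~ 1", {
  counts <- sapply(1:500, function(i) length(poisson_train(2, 10000, seed = i)))
  expect_equal(mean(counts), 20, tolerance = 0.05)
  expect_equal(var(counts), 20, tolerance = 0.2)
  isis <- unlist(lapply(1:50, function(i) diff(poisson_train(20, 60000, seed = i))))
  expect_equal(sd(isis) / mean(isis), 1, tolerance = 0.05)
  expect_length(poisson_train(0, 1000, seed = 1), 0)
  expect_error(poisson_train(-1, 1000), ">= 0")
})

test_that("theta modulation amplitude follows A = off/(1/d - 1)", {
  expect_equal(theta_amplitude(2, 0.7), 2 / (1 / 0.7 - 1))
  expect_equal(theta_amplitude(2, 0.7), 14 / 3, tolerance = 1e-12)
})

test_that("vanishing depth reduces the theta train to homogeneous Poisson", {
  tt <- theta_modulated_train(8, off = 20, depth = 0.01, duration_ms = 60000,
                              seed = 11)
  set.seed(12)
  tt <- tt + runif(length(tt), 0, 0.1)   # de-quantise the dt grid (KS ties)
  isis <- diff(tt)
  ks <- stats::ks.test(isis, "pexp", rate = 1 / mean(isis))
  expect_gt(ks$p.value, 0.01)
  expect_equal(length(tt) / 60, 20, tolerance = 0.1)
})

test_that("rate fit of a long theta-modulated train recovers f and depth", {
  set.seed(42)
  trains <- lapply(1:100, function(i)
    theta_modulated_train(8, off = 2, depth = 0.7, duration_ms = 20000, seed = i))
  tt <- unlist(trains)
  bins <- seq(0, 20000, by = 1)
  h <- hist(tt, breaks = bins, plot = FALSE)$counts / 100 / 1e-3   # Hz
  t <- bins[-1] - 0.5
  # fit sinusoid at 8 Hz by linear regression on sin/cos regressors
  X <- cbind(1, sin(2 * pi * 8 * t / 1000), cos(2 * pi * 8 * t / 1000))
  cf <- stats::lm.fit(X, h)$coefficients
  A_hat <- sqrt(cf[2]^2 + cf[3]^2)
  # oracle: fundamental Fourier amplitude of the rectified sinusoidal rate
  A <- theta_amplitude(2, 0.7)
  th <- seq(0, 2 * pi, by = 1e-4)
  A_theo <- 2 * mean(pmax(A * sin(th) + 2, 0) * sin(th))
  expect_equal(unname(A_hat), A_theo, tolerance = 0.1)
  # frequency recovery: spectrum of the binned rate peaks at 8 Hz
  psd <- welch_psd(h - mean(h), fs = 1000, window_sec = 2)
  expect_equal(peak_power(psd, c(4, 12))$freq, 8, tolerance = 0.5)
})

test_that("pooled theta-train spike phases are unimodal at the sine peak", {
  set.seed(7)
  tt <- unlist(lapply(1:200, function(i)
    theta_modulated_train(8, off = 2, depth = 0.7, duration_ms = 10000, seed = i)))
  ph <- (360 * 8 * tt / 1000) %% 360   # 90 deg = sine peak
  cm <- circ_mean(ph)
  expect_equal(cm$mean_deg, 90, tolerance = 5)
  expect_gt(cm$resultant, 0.3)
})

test_that("jittered rhythmic generator: exact period at sigma 0; ISI stats at default sigma", {
  tt <- jittered_rhythmic_times(125, 0, 10, seed = 1)
  expect_equal(tt, 125 * (1:10))
  tt <- jittered_rhythmic_times(125, 17.7, 10001, seed = 2)
  isis <- diff(tt)
  expect_equal(mean(isis), 125, tolerance = 0.02)
  expect_equal(sd(isis), 17.7 * sqrt(2), tolerance = 0.05)
})

test_that("OU conductance matches its stationary moments and autocorrelation", {
  g <- ou_conductance(0.0032, 0.003, tau = 2.7, duration_ms = 200000, dt_ms = 0.1,
                      seed = 3)
  expect_equal(mean(g), 0.0032, tolerance = 0.03)
  expect_equal(sd(g), 0.003, tolerance = 0.03)
  # autocorrelation time constant within 10%
  ac <- stats::acf(g, lag.max = 100, plot = FALSE)$acf
  lag1 <- which(ac < exp(-1))[1] - 1    # lags of 0.1 ms
  expect_equal(lag1 * 0.1, 2.7, tolerance = 0.1)
  expect_equal(ou_conductance(0.5, 0, tau = 5, duration_ms = 100, seed = 1),
               rep(0.5, 1000))
})

test_that("generators are reproducible per seed and independent across ids", {
  a <- poisson_train(5, 5000, seed = 123)
  b <- poisson_train(5, 5000, seed = 123)
  expect_identical(a, b)
  c1 <- poisson_train(5, 5000, seed = 124)
  expect_false(identical(a, c1))
})

test_that("the input factory keys VP/SI regimes by case", {
  net <- tiny_network(seed = 1, scale = 0.05)
  for (case in 1:6) {
    inp <- make_case_inputs(net, case, 2000, seed = 1)
    expected <- if (case %in% 2:4) "theta" else "baseline"
    expect_identical(inp$regime, expected)
    if (expected == "theta") {
      # every afferent fires near once per 125 ms cycle
      rates <- vapply(inp$vpsi, function(t) length(t) / 2, 0)
      expect_equal(mean(rates), 8, tolerance = 0.15)
    }
  }
})
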