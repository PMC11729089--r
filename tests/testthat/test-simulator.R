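# Network integration: silence, determinism, rates, causality, charge
# consistency, step-size robustness.

test_that("a network with no afferents and no background stays silent at rest", {
  net <- tiny_network(seed = 1, scale = 0.05)
  sim <- run_simulation(net, NULL, duration_ms = 500, seed = 1, ou = FALSE,
                        lfp = FALSE)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("identical seeds give identical results (bitwise)", {
  net <- tiny_network(seed = 3, scale = 0.1)
  inputs <- make_case_inputs(net, 2, 1500, seed = 3)
  a <- run_simulation(net, inputs, duration_ms = 1500, seed = 3)
  b <- run_simulation(net, inputs, duration_ms = 1500, seed = 3)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  c1 <- run_simulation(net, inputs, duration_ms = 1500, seed = 4)
  expect_false(identical(a$spikes, c1$spikes))
})

test_that("firing_rates computes count / retained duration by type", {
  spikes <- data.frame(time_ms = seq(500, 10000, length.out = 10),
                       cell_id = 1, cell_type = "PN_A")
  out <- firing_rates(spikes, discard_ms = 0, duration_ms = 10000,
                      types = c("PN_A", "PV"))
  expect_equal(out$mean_hz[out$type == "PN_A"], 1)
  expect_equal(out$mean_hz[out$type == "PV"], 0)
  expect_error(firing_rates(spikes, discard_ms = 10000, duration_ms = 10000,
                            types = "PN_A"), "window")
})

test_that("no synaptic effect precedes the presynaptic spike plus its delay", {
  delay <- 5
  net <- toy_network(w = 5, delay_ms = delay)
  # drive the PN with a single strong afferent-like event via a thalamic source
  net$afferents$thalamic <- data.frame(source = 1L, post = 1L, weight = 150)
  inputs <- list(vpsi = NULL, thalamic = list(c(50)))
  sim <- run_simulation(net, inputs, duration_ms = 120, seed = 1, ou = FALSE,
                        lfp = FALSE, record_v = 1:2)
  expect_gte(nrow(sim$spikes), 1)
  t_pre <- sim$spikes$time_ms[sim$spikes$cell_id == 1][1]
  v_pv <- sim$v[2, ]
  t <- seq_len(ncol(sim$v)) * sim$v_dt_ms
  # before delivery the PV trace only shows the slow settling drift; the
  # EPSP onset after spike + delay is orders of magnitude steeper
  slope_before <- max(abs(diff(v_pv[t <= t_pre + delay - 2 * sim$v_dt_ms])))
  expect_lt(slope_before, 0.01)
  after <- v_pv[t > t_pre + delay & t < t_pre + delay + 5]
  expect_gt(max(abs(diff(after))), 0.05)
})

test_that("transmembrane currents sum to zero without electrode current", {
  net <- tiny_network(seed = 5, scale = 0.05)
  inputs <- make_case_inputs(net, 1, 800, seed = 5)
  sim <- run_simulation(net, inputs, duration_ms = 800, seed = 5,
                        record_currents = TRUE)
  expect_lt(max(abs(colSums(sim$i_binned))), 1e-9)
})

test_that("population rates are robust to halving the integration step", {
  net <- build_network(bla_cfg, seed = 6, scale = 0.25)
  inputs <- make_case_inputs(net, 1, 5000, seed = 6)
  r1 <- firing_rates(run_simulation(net, inputs, duration_ms = 5000, seed = 6,
                                    dt_ms = 0.1, lfp = FALSE),
                     discard_ms = 1000)
  r2 <- firing_rates(run_simulation(net, inputs, duration_ms = 5000, seed = 6,
                                    dt_ms = 0.05, lfp = FALSE),
                     discard_ms = 1000)
  pop1 <- sum(r1$mean_hz * r1$n_cells) / sum(r1$n_cells)
  pop2 <- sum(r2$mean_hz * r2$n_cells) / sum(r2$n_cells)
  expect_equal(pop1, pop2, tolerance = 0.05)
})

test_that("rates are stationary across discard-window shifts", {
  net <- build_network(bla_cfg, seed = 7, scale = 0.25)
  inputs <- make_case_inputs(net, 1, 6000, seed = 7)
  sim <- run_simulation(net, inputs, duration_ms = 6000, seed = 7, lfp = FALSE)
  r1 <- firing_rates(sim, discard_ms = 1000)
  sp2 <- sim$spikes[sim$spikes$time_ms <= 3500, ]
  r2 <- firing_rates(sp2, discard_ms = 1000, duration_ms = 3500,
                     types = sim$types)
  pn1 <- r1$mean_hz[r1$type == "PN_A"]
  pn2 <- r2$mean_hz[r2$type == "PN_A"]
  expect_equal(pn1, pn2, tolerance = 0.5)   # within sampling error at ~0.5 Hz
})

test_that("run round-trips losslessly through a run directory", {
  net <- tiny_network(seed = 8, scale = 0.05)
  inputs <- make_case_inputs(net, 1, 1000, seed = 8)
  sim <- run_simulation(net, inputs, duration_ms = 1000, seed = 8)
  dir <- tempfile()
  write_run(sim, dir, run_manifest(bla_cfg, seed = 8, case = 1))
  back <- read_run(dir)
  expect_equal(back$spikes$time_ms, sim$spikes$time_ms)
  expect_equal(back$spikes$cell_id, sim$spikes$cell_id)
  expect_equal(back$lfp, sim$lfp)
  expect_equal(back$manifest$seed, 8)
  expect_equal(back$manifest$config$populations$PV$count, 93)
})
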