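# Receptor kinetics, Mg block, cholinergic scaling, short-term plasticity.

test_that("receptor open fraction decays as r0*exp(-beta*t) with no transmitter", {
  spec <- synapse_spec("AMPA")
  st <- synapse_state(); st$r <- 0.8
  dt <- 0.01
  for (k in 1:500) st <- step_receptor(st, spec, dt, t = k * dt)
  expect_equal(st$r, 0.8 * exp(-spec$beta * 5), tolerance = 1e-6)
})

test_that("held-open receptor approaches alphaTmax/(alphaTmax+beta)", {
  spec <- synapse_spec("AMPA", on_dur = 1e6)
  st <- synapse_state()
  st <- step_receptor(st, spec, dt = 0.1, t = 0, spike = TRUE)
  for (k in 1:5000) st <- step_receptor(st, spec, dt = 0.1, t = k * 0.1)
  expect_equal(st$r, spec$alphaTmax / (spec$alphaTmax + spec$beta),
               tolerance = 1e-6)
})

test_that("r stays in [0,1] under 1 kHz bombardment", {
  spec <- synapse_spec("GABA_A")
  st <- synapse_state()
  for (k in 0:2000) {
    st <- step_receptor(st, spec, dt = 0.1, t = k * 0.1,
                        spike = (k %% 10) == 0)
    expect_true(st$r >= 0 && st$r <= 1)
  }
  expect_gt(st$r, 0.5)   # saturated under sustained drive
})

test_that("NMDA Mg block and cholinergic scaling follow their closed forms", {
  expect_equal(mg_block(0), 1 / 1.33, tolerance = 1e-12)
  expect_equal(ach_factor(0.3, 1), 1)
  expect_equal(ach_factor(0.3, 2), 1.3)
  expect_equal(ach_factor(0.3, 0), 0.7)
  expect_error(ach_factor(0.3, -0.2), "0, 1 or 2")
  spec <- synapse_spec("AMPA", b_ACh = 0.3)
  st <- synapse_state(); st$r <- 0.5
  i1 <- synaptic_current(st, spec, w = 1, V_post = -60, ACh = 1)
  expect_equal(synaptic_current(st, spec, 1, -60, ACh = 2), 1.3 * i1)
  expect_equal(synaptic_current(st, spec, 1, -60, ACh = 0), 0.7 * i1)
  # zero current at reversal, for any gating state
  expect_equal(synaptic_current(st, spec, 1, spec$E, ACh = 1), 0)
})

test_that("ACh scaling leaves the GABA_A reversal unchanged and is linear in (ACh-1)", {
  spec <- synapse_spec("GABA_A", b_ACh = 0.3)
  st <- synapse_state(); st$r <- 0.4
  expect_equal(synaptic_current(st, spec, 1, spec$E, ACh = 2), 0)
  i0 <- synaptic_current(st, spec, 1, -60, 1)
  d_up <- synaptic_current(st, spec, 1, -60, 2) - i0
  d_dn <- i0 - synaptic_current(st, spec, 1, -60, 0)
  expect_equal(d_up, d_dn, tolerance = 1e-12)
})

test_that("facilitation jumps to f and recovers toward 1", {
  rule <- stp_rule("facilitating", f = 1.5, tau_F = 150)
  st <- synapse_state()
  st <- stp_on_spike(st, rule, 0)
  expect_equal(st$F, 1.5)
  expect_equal(stp_multiplier(st, rule, 300), 1 + 0.5 * exp(-2),
               tolerance = 1e-12)
  expect_equal(stp_multiplier(st, rule, 1e6), 1, tolerance = 1e-9)
})

test_that("two-spike depression matches the closed-form oracle", {
  d1 <- 0.95; d2 <- 0.9; t1 <- 40; t2 <- 70; dt <- 20
  rule <- stp_rule("depressing", d1 = d1, d2 = d2, tau_D1 = t1, tau_D2 = t2)
  st <- synapse_state()
  st <- stp_on_spike(st, rule, 0)
  st <- stp_on_spike(st, rule, dt)
  # each D recovers from d toward 1, then multiplies by d again
  D1 <- (1 + (d1 - 1) * exp(-dt / t1)) * d1
  D2 <- (1 + (d2 - 1) * exp(-dt / t2)) * d2
  expect_equal(st$D1, D1, tolerance = 1e-12)
  expect_equal(st$D2, D2, tolerance = 1e-12)
  expect_error(stp_on_spike(st, rule, dt - 5), "non-decreasing")
})

test_that("paired-pulse ratio at 20 ms: facilitating > 1, depressing < 1", {
  fac <- stp_rule("facilitating", f = 1.5, tau_F = 150)
  dep <- stp_rule("depressing", d1 = 0.95, d2 = 0.9, tau_D1 = 40, tau_D2 = 70)
  for (rule in list(fac, dep)) {
    st <- synapse_state()
    st <- stp_on_spike(st, rule, 0)
    m1 <- stp_multiplier(st, rule, 0)
    st <- stp_on_spike(st, rule, 20)
    m2 <- stp_multiplier(st, rule, 20)
    if (rule$kind == "facilitating") expect_gt(m2 / m1, 1)
    else expect_lt(m2 / m1, 1)
  }
})

test_that("depressing multiplier is capped at 1 and facilitating F stays >= 1", {
  dep <- stp_rule("depressing", d1 = 0.95, d2 = 0.9)
  st <- synapse_state()
  expect_equal(stp_multiplier(st, dep, 0), 1)   # no spikes ever
  fac <- stp_rule("facilitating", f = 1.5, tau_F = 150)
  st <- synapse_state()
  for (t in seq(0, 500, by = 10)) {
    st <- stp_on_spike(st, fac, t)
    expect_gte(st$F, 1)
  }
})

test_that("single-spike conductance shows the dual-exponential rise/decay regimes", {
  spec <- synapse_spec("AMPA")
  st <- synapse_state()
  dt <- 0.01
  r <- numeric(1000)
  for (k in 1:1000) {
    st <- step_receptor(st, spec, dt, t = (k - 1) * dt, spike = k == 1)
    r[k] <- st$r
  }
  t <- (1:1000) * dt
  # decay phase: fit log r after the pulse -> rate beta within 10%
  sel <- t > 2 & t <= 8
  fit <- stats::lm(log(r[sel]) ~ t[sel])
  expect_equal(-unname(stats::coef(fit)[2]), spec$beta, tolerance = 0.1)
  # rise phase rate ~ alphaTmax + beta within 10% (log approach to plateau)
  rinf <- spec$alphaTmax / (spec$alphaTmax + spec$beta)
  sel <- t <= 0.9
  fit <- stats::lm(log(1 - r[sel] / rinf) ~ t[sel])
  expect_equal(-unname(stats::coef(fit)[2]), spec$alphaTmax + spec$beta,
               tolerance = 0.1)
})
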