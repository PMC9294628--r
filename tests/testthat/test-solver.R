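# Backward-Euler stepping, spike detection, protocol running.

test_that("the grid, determinism and trace shapes are exact", {
  p <- stimulus_protocol(2000, dt = 0.1, ie_soma = 1)
  s <- simulate_neuron(p)
  expect_length(s$v_soma, 20001)
  expect_length(s$time, 20001)
  expect_equal(s$time[2] - s$time[1], 0.1)
  s2 <- simulate_neuron(p)
  expect_identical(s$v_soma, s2$v_soma)
  expect_identical(s$spikes_soma, s2$spikes_soma)
  expect_true(all(diff(s$spikes_soma) > 0))
})

test_that("the numerically located resting equilibrium is a fixed point", {
  p <- hh_parameters()
  iss <- function(V) {
    eq <- gating_equilibrium(V)
    somatic_membrane_current(V, list(m = eq$m_inf, h = eq$h_inf,
                                     n = eq$n_inf), p)
  }
  Vstar <- stats::uniroot(iss, c(-75, -55), tol = 1e-14)$root
  eq <- gating_equilibrium(Vstar)
  st <- list(V = Vstar, m = eq$m_inf, h = eq$h_inf, n = eq$n_inf)
  st1 <- step_single(st, Ie = 0)
  expect_lt(abs(st1$V - Vstar), 1e-9)
})

test_that("single-spike and repetitive regimes appear at the published currents", {
  s1 <- simulate_neuron(stimulus_protocol(2000, ie_soma = 0.3))
  expect_length(s1$spikes_soma, 1)
  s2 <- simulate_neuron(stimulus_protocol(2000, ie_soma = 3))
  expect_gte(length(s2$spikes_soma), 5)
})

test_that("the passive limit reproduces the implicit RC update exactly", {
  par <- neuron_parameters(hh = hh_parameters(gNa = 0, gK = 0))
  st <- list(V = -60, m = 0.1, h = 0.6, n = 0.3)
  out <- step_single(st, Ie = 0.5, dt = 0.1, params = par)
  gl <- 0.3; el <- -54.3; cmdt <- 1 / 0.1
  ie <- 0.1 * 0.5 / 0.01                       # nA -> uA/cm2 at A = 0.01 mm2
  expect_equal(out$V, (cmdt * (-60) + gl * el + ie) / (cmdt + gl),
               tolerance = 1e-12)
  # and over many steps it follows the discrete RC recursion
  v <- -60
  stn <- st
  for (k in 1:200) {
    stn <- step_single(stn, Ie = 0.5, dt = 0.1, params = par)
    v <- (cmdt * v + gl * el + ie) / (cmdt + gl)
  }
  expect_lt(abs(stn$V - v), 1e-9)
})

test_that("backward Euler stays bounded for large dt and strong drive", {
  for (dt in c(0.1, 0.5, 1)) for (ie in c(0, 5, 10)) {
    s <- simulate_neuron(stimulus_protocol(500, dt = dt, ie_soma = ie))
    expect_true(all(s$v_soma > -120 & s$v_soma < 80))
  }
})

test_that("halving dt preserves onset timing and overall firing rate", {
  a <- simulate_neuron(stimulus_protocol(2000, dt = 0.1, ie_soma = 3))
  b <- simulate_neuron(stimulus_protocol(2000, dt = 0.05, ie_soma = 3))
  # the first spike is locked to within 0.2 ms; later spikes drift in phase
  # at first order in dt, so the rate - not each spike time - is compared
  expect_lt(abs(a$spikes_soma[1] - b$spikes_soma[1]), 0.2)
  expect_lt(abs(length(a$spikes_soma) - length(b$spikes_soma)) /
              length(a$spikes_soma), 0.05)
})

test_that("spike detection crosses upward with hysteresis", {
  expect_identical(detect_spikes(rep(-65, 100), 0.1), numeric(0))
  v <- c(rep(-65, 10), rep(-10, 50), rep(-65, 10))   # plateau counts once
  expect_equal(detect_spikes(v, 0.1), 0.1 * 10)
  v2 <- c(-65, -10, -65, -10, -65)                   # two crossings
  expect_equal(detect_spikes(v2, 0.1), c(0.1, 0.3))
  expect_error(detect_spikes(numeric(0)), "empty")
})

test_that("decoupled two-compartment steps equal single-compartment steps exactly", {
  par <- neuron_parameters(geometry = geometry_parameters(g_ds = 0, g_sd = 0))
  soma <- default_gate_state(-58)
  dend <- list(V = -45)
  out2 <- step_two(soma, dend, Ie_s = 1, Ie_d = 0.2, params = par)
  out1 <- step_single(soma, Ie = 1, params = par)
  expect_identical(out2$soma$V, out1$V)
  expect_identical(out2$soma$m, out1$m)
  expect_identical(out2$soma$n, out1$n)
  # the decoupled dendrite is blind to somatic drive
  out3 <- step_two(soma, dend, Ie_s = 10, Ie_d = 0.2, params = par)
  expect_identical(out2$dend$V, out3$dend$V)
})

test_that("dendritic drive fires the dendrite first, somatic drive leaves it silent", {
  s <- simulate_neuron(stimulus_protocol(2000, ie_dend = 3), model = "two")
  expect_gt(length(s$dcaap_onsets), 0)
  expect_gt(length(s$spikes_soma), 0)
  expect_lt(s$dcaap_onsets[1], s$spikes_soma[1])
  # inter-dCaAP intervals equal within one timestep under constant drive
  expect_lt(diff(range(diff(s$dcaap_onsets))), 0.1 + 1e-9)

  s2 <- simulate_neuron(stimulus_protocol(2000, ie_soma = 10), model = "two")
  expect_gt(length(s2$spikes_soma), 0)
  expect_length(s2$dcaap_onsets, 0)
})

test_that("somatic spike frequency is non-decreasing in somatic drive", {
  f <- vapply(c(1, 2, 3, 5, 7), function(i)
    length(simulate_neuron(stimulus_protocol(2000, ie_soma = i))$spikes_soma),
    numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("two-compartment voltages equalize when compartments agree", {
  # V_soma = V_dend at rest with symmetric coupling: coupling currents are
  # zero, so the coupled update equals the uncoupled one
  par <- neuron_parameters()
  par0 <- neuron_parameters(geometry = geometry_parameters(g_ds = 0, g_sd = 0))
  soma <- default_gate_state(-65)
  dend <- list(V = -65)
  a <- step_two(soma, dend, params = par)
  b <- step_two(soma, dend, params = par0)
  # the implicit solve evaluates coupling at the end-of-step voltages, so
  # the residual is bounded by g |dVd - dVs| dt / Cm, not exactly zero
  expect_equal(a$soma$V, b$soma$V, tolerance = 1e-4)
})
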