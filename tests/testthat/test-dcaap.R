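# Dendritic calcium action potential: trigger, amplitude factor, waveform.

test_that("trigger obeys threshold and refractory semantics", {
  p <- dcaap_parameters()
  # exactly at threshold: K = exp(0) = 1
  st <- dcaap_trigger(p$V_thresh, 0, dcaap_state(), p)
  expect_true(st$active)
  expect_equal(st$K_at_activation, 1)
  expect_equal(st$t_prime, 0)
  # below threshold: nothing happens
  st2 <- dcaap_trigger(p$V_thresh - 0.001, 0, dcaap_state(), p)
  expect_false(st2$active)
  # within the refractory period re-activation is forbidden
  st3 <- dcaap_trigger(0, 150, st, p)   # 150 ms after activation
  expect_equal(st3$t_prime, 0)
  # at 200 ms it is eligible again
  st4 <- dcaap_trigger(-30, 200, st, p)
  expect_equal(st4$t_prime, 200)
  expect_equal(st4$K_at_activation, exp(-(1 / 18.3) * 6 / 0.3))
})

test_that("K decreases strictly with activation overshoot", {
  p <- dcaap_parameters()
  over <- seq(0, 40, by = 2.5)
  K <- vapply(over, function(o)
    dcaap_trigger(p$V_thresh + o, 0, dcaap_state(), p)$K_at_activation,
    numeric(1))
  expect_true(all(diff(K) < 0))
  expect_equal(K[1], 1)
})

test_that("ab waveform rises, peaks inside the support, then vanishes", {
  expect_equal(ab_waveform(0), hp$ab_0, tolerance = 1e-12)
  expect_equal(ab_waveform(10.5), hp$ab_10p5, tolerance = 1e-12)
  # interior maximum: value at dt'/2 exceeds both endpoints of the support
  expect_gt(ab_waveform(10.5), ab_waveform(0))
  expect_gt(ab_waveform(10.5), ab_waveform(42))
  # long after activation both sigmoids saturate
  expect_lt(ab_waveform(200), 1e-9)
  expect_lt(ab_waveform(300), 1e-9)
  # never negative, bounded below 1
  t <- seq(0, 250, by = 0.05)
  v <- ab_waveform(t)
  expect_true(all(v >= 0 & v < 1))
  expect_error(ab_waveform(-0.1), "non-negative")
})

test_that("dCaAP current follows -omega K (A-B) with cutoff", {
  p <- dcaap_parameters()
  expect_identical(dcaap_current(dcaap_state(), 50, p), 0)
  st <- dcaap_state(active = TRUE, t_prime = 0, K_at_activation = 1)
  expect_equal(dcaap_current(st, 0, p), -3 * 1 * ab_waveform(0))
  # K = 1, A-B = 0.5, omega = 3 -> -1.5
  expect_equal(dcaap_current(st, 0, p), -1.5, tolerance = 1e-12)
  # waveform has decayed below threshold long after activation -> exact 0
  expect_identical(dcaap_current(st, 240, p), 0)
  expect_error(dcaap_current(st, -1, p), "precedes")
})

test_that("larger dendritic overshoot at activation gives smaller current", {
  p <- dcaap_parameters()
  cur <- vapply(c(1, 5), function(over) {
    st <- dcaap_trigger(p$V_thresh + over, 0, dcaap_state(), p)
    abs(dcaap_current(st, 10.5, p))
  }, numeric(1))
  expect_lt(cur[2], cur[1])
})

test_that("dendritic membrane current is leak plus scaled dCaAP current", {
  hh <- hh_parameters(); p <- dcaap_parameters()
  expect_equal(dendritic_membrane_current(hh$EL, dcaap_state(), 0, hh, p), 0)
  st <- dcaap_state(active = TRUE, t_prime = 0, K_at_activation = 1)
  expect_equal(dendritic_membrane_current(hh$EL, st, 0, hh, p, scale = 1),
               -1.5, tolerance = 1e-12)
  expect_equal(dendritic_membrane_current(hh$EL, st, 0, hh, p, scale = 80),
               -120, tolerance = 1e-9)
  # between waveform end and the next trigger the dendrite is purely passive
  expect_equal(dendritic_membrane_current(-50, st, 100, hh, p, scale = 80),
               1000 * hh$gL * (-50 - hh$EL))
})

test_that("no two activations occur closer than the refractory period", {
  # strong constant drive retriggers exactly at refractory expiry
  for (i in c(0.2, 1, 3, 8)) {
    s <- simulate_neuron(stimulus_protocol(1500, ie_dend = i), model = "two")
    if (length(s$dcaap_onsets) > 1)
      expect_gte(min(diff(s$dcaap_onsets)), 200)
  }
  # a synaptic drive with events inside the refractory window cannot
  # re-trigger either
  ev <- seq(0, 450, by = 50)
  s <- simulate_neuron(stimulus_protocol(500, syn_dend = rep(list(ev), 25)),
                       model = "two")
  if (length(s$dcaap_onsets) > 1)
    expect_gte(min(diff(s$dcaap_onsets)), 200)
})
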