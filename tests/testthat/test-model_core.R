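# Ion-channel kinetics, gating updates and synapse model.

test_that("rate constants reproduce the closed forms and their limits", {
  r <- rate_constants(-65)
  expect_equal(r$beta_n, 0.125)     # exp(0)
  expect_equal(r$alpha_h, 0.07)     # exp(0)
  expect_equal(rate_constants(-55)$alpha_n, 0.1)  # removable singularity
  expect_equal(rate_constants(-40)$alpha_m, 1.0)  # removable singularity
  expect_equal(rate_constants(-35)$beta_h, 0.5)   # logistic midpoint

  # continuity across the singular voltages
  expect_lt(abs(rate_constants(-55 + 1e-6)$alpha_n - 0.1), 1e-5)
  expect_lt(abs(rate_constants(-55 - 1e-6)$alpha_n - 0.1), 1e-5)
  expect_lt(abs(rate_constants(-40 + 1e-6)$alpha_m - 1.0), 1e-5)

  # agreement with the independently written forms on a grid
  V <- seq(-99.5, 99.5, by = 7.3)
  r <- rate_constants(V)
  o <- oracle_rates(V)
  for (nm in names(o)) expect_equal(r[[nm]], o[[nm]], tolerance = 1e-12)
  expect_true(all(as.matrix(r) >= 0 & is.finite(as.matrix(r))))

  expect_error(rate_constants(NaN), "finite")
  expect_error(rate_constants(Inf), "finite")
})

test_that("gating equilibria match high-precision reference values", {
  eq <- gating_equilibrium(-65)
  expect_equal(eq$n_inf, hp$n_inf_m65, tolerance = 1e-14)
  expect_equal(eq$tau_n, hp$tau_n_m65, tolerance = 1e-14)
  expect_equal(eq$m_inf, hp$m_inf_m65, tolerance = 1e-14)
  expect_equal(eq$h_inf, hp$h_inf_m65, tolerance = 1e-14)
  expect_equal(eq$tau_h, hp$tau_h_m65, tolerance = 1e-14)

  V <- seq(-100, 100, by = 2.5)
  eq <- gating_equilibrium(V)
  expect_true(all(eq$n_inf > 0 & eq$n_inf < 1))
  expect_true(all(eq$m_inf > 0 & eq$m_inf < 1))
  expect_true(all(eq$h_inf > 0 & eq$h_inf < 1))
  expect_true(all(eq$tau_n > 0 & eq$tau_m > 0 & eq$tau_h > 0))
})

test_that("advance_gate is the exact one-step solution of the gate ODE", {
  # fixed point: x = x_inf stays put
  eq <- gating_equilibrium(-50)
  expect_equal(advance_gate(eq$n_inf, -50, 0.1, "n"), eq$n_inf)
  # dt -> 0 returns x
  expect_equal(advance_gate(0.42, -50, 1e-12, "m"), 0.42, tolerance = 1e-9)
  # single step against the RK4 brute-force oracle
  rk <- oracle_gate_rk4(0.2, -40, 0.1, dt_fine = 1e-4, gate = "n")
  expect_equal(advance_gate(0.2, -40, 0.1, "n"),
               rk$x[length(rk$x)], tolerance = 1e-6)
  expect_error(advance_gate(1.2, -40, 0.1, "n"), "\\[0, 1\\]")
})

test_that("gate closure and equilibrium convergence hold across state space", {
  set.seed(11)
  for (i in 1:50) {
    V <- runif(1, -100, 100)
    dt <- runif(1, 1e-3, 10)
    x <- runif(1)
    g <- sample(c("n", "m", "h"), 1)
    x1 <- advance_gate(x, V, dt, g)
    expect_gte(x1, 0); expect_lte(x1, 1)
    xi <- gating_equilibrium(V)[[paste0(g, "_inf")]]
    # result lies between x and x_inf
    expect_true((x1 - x) * (xi - x) >= 0 && abs(x1 - xi) <= abs(x - xi) + 1e-12)
  }
  # iterating at fixed V converges to x_inf
  x <- 0.9
  for (i in 1:400) x <- advance_gate(x, -62, 1, "n")
  expect_equal(x, gating_equilibrium(-62)$n_inf, tolerance = 1e-9)
})

test_that("gate trajectories at dt = 0.1 match the fine-dt RK4 oracle", {
  for (V in c(-70, -40)) for (g in c("n", "m", "h")) {
    rk <- oracle_gate_rk4(0.3, V, 50, dt_fine = 1e-4, gate = g)
    idx <- seq(1, length(rk$times), by = 1000)   # every 0.1 ms
    x <- 0.3
    traj <- numeric(length(idx)); traj[1] <- x
    for (k in 2:length(idx)) {
      x <- advance_gate(x, V, 0.1, g)
      traj[k] <- x
    }
    expect_lt(max(abs(traj - rk$x[idx])), 1e-4)
  }
})

test_that("somatic membrane current assembles leak, K and Na terms", {
  p <- hh_parameters()
  expect_equal(somatic_membrane_current(p$EL, list(m = 0, h = 0, n = 0), p), 0)
  # Na term vanishes at its reversal; K gate closed
  expect_equal(somatic_membrane_current(p$ENa, list(m = 1, h = 1, n = 0), p),
               1000 * p$gL * (p$ENa - p$EL))
  eq <- gating_equilibrium(-65)
  expect_equal(
    somatic_membrane_current(-65, list(m = eq$m_inf, h = eq$h_inf,
                                       n = eq$n_inf), p),
    hp$i_soma_m65_eq, tolerance = 1e-12)
  expect_error(
    somatic_membrane_current(-65, list(m = 2, h = 0.5, n = 0.5), p),
    "\\[0, 1\\]")
})

test_that("synaptic release probability and current follow the decay law", {
  expect_equal(synaptic_release_probability(0), 1)        # Pmax = 1 at event
  expect_equal(synaptic_release_probability(10), exp(-1)) # t = tau_s
  expect_lt(synaptic_release_probability(1000), 1e-40)
  expect_equal(synaptic_release_probability(NA), 0)       # never activated
  expect_error(synaptic_release_probability(-1), "non-negative")

  expect_equal(synaptic_current(0, 5), 0)                 # at reversal
  expect_equal(synaptic_current(-65, NA), 0)              # no event ever
  expect_equal(synaptic_current(-65, 0), 0.05 * 1 * (-65 - 0))
})

test_that("the stepper's recursive release decay matches the closed form", {
  # one synapse, single event at t = 0, no conductance effect (gmax = 0
  # would remove it; use tiny gmax and track via an analytic comparison of
  # the voltage instead: easier to compare Ps through the current it drives)
  p <- neuron_parameters(synapse = synapse_parameters(gmax = 0.05))
  prot <- stimulus_protocol(100, settle = 0, syn_dend = list(0))
  s <- simulate_neuron(prot, model = "two", params = p)
  fs <- s$final_state
  # release is reset at the end of the step containing the event, so at
  # time t the recursion has applied (t - te)/dt - 1 decay factors
  expect_equal(fs$ps_dend, synaptic_release_probability(100 - 0.1),
               tolerance = 1e-10)
})
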