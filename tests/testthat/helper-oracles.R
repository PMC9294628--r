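# Independent oracles used across the suite.  These re-derive expected
# values through routes that do not share code with the package internals.

# HH rate functions written out independently (plain closed forms; the
# removable singularities are simply avoided by the test voltages)
oracle_rates <- function(V) {
  # analytic limits at the removable singularities (the mathematical
  # definition of the rate there, not shared implementation code)
  an <- ifelse(abs(V + 55) < 1e-12, 0.1,
               0.01 * (V + 55) / (1 - exp(-0.1 * (V + 55))))
  am <- ifelse(abs(V + 40) < 1e-12, 1.0,
               0.1 * (V + 40) / (1 - exp(-0.1 * (V + 40))))
  list(
    alpha_n = an,
    beta_n  = 0.125 * exp(-0.0125 * (V + 65)),
    alpha_m = am,
    beta_m  = 4 * exp(-0.0556 * (V + 65)),
    alpha_h = 0.07 * exp(-0.05 * (V + 65)),
    beta_h  = 1 / (1 + exp(-0.1 * (V + 35))))
}

# brute-force gate trajectory: classical 4th-order Runge-Kutta on
# tau dx/dt = x_inf - x at fixed voltage, implemented via deSolve's compiled
# rk4 integrator
oracle_gate_rk4 <- function(x0, V, t_end, dt_fine = 1e-4,
                            gate = c("n", "m", "h")) {
  gate <- match.arg(gate)
  r <- oracle_rates(V)
  a <- r[[paste0("alpha_", gate)]]
  b <- r[[paste0("beta_", gate)]]
  deriv <- function(t, y, parms) list(a * (1 - y) - b * y)
  times <- seq(0, t_end, by = dt_fine)
  out <- deSolve::rk4(y = c(x = x0), times = times, func = deriv,
                      parms = NULL)
  list(times = out[, 1], x = out[, 2])
}

# high-precision reference values, frozen from a 40-digit evaluation of the
# same closed forms in an independent arbitrary-precision system
hp <- list(
  n_inf_m65 = 0.31767691406069739,
  tau_n_m65 = 5.45858468751442088,
  m_inf_m65 = 0.052932485257249575,
  tau_m_m65 = 0.23676687868568761,
  h_inf_m65 = 0.59612075350846024,
  tau_h_m65 = 8.51601076440657488,
  i_soma_m65_eq = -0.030323709182496443,  # uA/cm2, gates at equilibrium
  ab_0 = 0.5,                              # to 1e-21
  ab_10p5 = 0.97068776924466472,
  e_s1615 = 2.718292236328125)             # nearest s16.15 to exp(1)

default_gate_state <- function(V = -65) {
  eq <- gating_equilibrium(V)
  list(V = V, m = eq$m_inf, h = eq$h_inf, n = eq$n_inf)
}

# exact integer round-to-nearest (ties away from zero) used as the
# fixed-point oracle; num and den are exact doubles well inside 2^53
oracle_div_round <- function(num, den) {
  q <- num / den
  f <- floor(q)
  r <- q - f
  if (r > 0.5 || (r == 0.5 && q >= 0)) f + 1
  else if (r < 0.5 || (r == 0.5 && q < 0)) f
  else f
}
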