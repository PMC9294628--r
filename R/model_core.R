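#' Voltage-dependent channel transition rates
#'
#' The six opening/closing rates of the HH K+ activation (n), Na+ activation
#' (m) and Na+ inactivation (h) gates, in 1/ms. The two removable
#' singularities (alpha_n at V = -55 mV, alpha_m at V = -40 mV) are evaluated
#' by their analytic limits whenever the denominator argument is within 1e-7
#' of zero.
#'
#' @param V membrane voltage (mV), may be a vector
#' @return a data.frame with columns `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h`
#' @examples
#' rate_constants(-65)
#' @export
rate_constants <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric")
  as.data.frame(cpp_rate_constants(as.numeric(V)))
}

#' Gating equilibria and time constants
#'
#' For each gate x in {n, m, h}: x_inf = alpha/(alpha+beta) and
#' tau_x = 1/(alpha+beta) (ms).
#'
#' @inheritParams rate_constants
#' @return a data.frame with columns `n_inf`, `tau_n`, `m_inf`, `tau_m`,
#'   `h_inf`, `tau_h`
#' @examples
#' gating_equilibrium(-65)
#' @export
gating_equilibrium <- function(V) {
  r <- rate_constants(V)
  data.frame(
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_n = 1 / (r$alpha_n + r$beta_n),
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    tau_h = 1 / (r$alpha_h + r$beta_h)
  )
}

#' Advance one gating variable by one timestep
#'
#' Exact solution of the first-order gate kinetics over a step during which
#' the voltage is held fixed ("conditional linearity"):
#' x' = x_inf + (x - x_inf) exp(-dt/tau_x). The result is a convex
#' combination of `x` and `x_inf(V)` and therefore stays in \[0, 1\].
#'
#' @param x current gate value in \[0, 1\]
#' @param V membrane voltage (mV) held over the step
#' @param dt timestep (ms)
#' @param gate which gate, one of `"n"`, `"m"`, `"h"`
#' @return the updated gate value
#' @examples
#' advance_gate(0.2, -40, 0.1, "m")
#' @export
advance_gate <- function(x, V, dt, gate = c("n", "m", "h")) {
  gate <- match.arg(gate)
  if (any(x < 0 | x > 1)) stop("gate value outside [0, 1]")
  stopifnot(dt > 0)
  eq <- gating_equilibrium(V)
  xinf <- eq[[paste0(gate, "_inf")]]
  tau <- eq[[paste0("tau_", gate)]]
  xinf + (x - xinf) * exp(-dt / tau)
}

#' Somatic ionic membrane current density
#'
#' Sum of leak, delayed-rectifier K+ and transient Na+ currents,
#' gL (V-EL) + gK n^4 (V-EK) + gNa m^3 h (V-ENa), returned in uA/cm2
#' (conductances are converted from S/cm2 to mS/cm2 internally).
#'
#' @param V membrane voltage (mV)
#' @param gates list or data.frame with elements `m`, `h`, `n`
#' @param p [hh_parameters()]
#' @return current density (uA/cm2); positive = outward
#' @examples
#' somatic_membrane_current(-65, list(m = 0.05, h = 0.6, n = 0.32))
#' @export
somatic_membrane_current <- function(V, gates, p = hh_parameters()) {
  stopifnot(inherits(p, "hh_parameters"))
  if (any(unlist(gates[c("m", "h", "n")]) < 0) ||
      any(unlist(gates[c("m", "h", "n")]) > 1))
    stop("gate values outside [0, 1]")
  1000 * p$gL * (V - p$EL) +
    1000 * p$gK * gates$n^4 * (V - p$EK) +
    1000 * p$gNa * gates$m^3 * gates$h * (V - p$ENa)
}

#' Probability of neurotransmitter release
#'
#' Ps = Pmax exp(-t/tau_s) where `t` is the time since the most recent
#' presynaptic event; a synapse that has never been activated has Ps = 0.
#'
#' @param t_since_event time since the last presynaptic event (ms), `NA` or
#'   `Inf` for "never activated"
#' @param p [synapse_parameters()]
#' @return release probability in \[0, Pmax\]
#' @examples
#' synaptic_release_probability(10)  # Pmax * exp(-1)
#' @export
synaptic_release_probability <- function(t_since_event, p = synapse_parameters()) {
  stopifnot(inherits(p, "synapse_parameters"))
  t <- t_since_event
  never <- is.na(t) | is.infinite(t)
  if (any(t[!never] < 0)) stop("t_since_event must be non-negative")
  out <- ifelse(never, 0, p$Pmax * exp(-t / p$tau_s))
  out
}

#' Synaptic current density of one synapse
#'
#' Isyn = gmax Ps (V - Esyn) in uA/cm2 (gmax in mS/cm2). The caller sums over
#' all synapses on a compartment.
#'
#' @param V membrane voltage (mV)
#' @inheritParams synaptic_release_probability
#' @return current density (uA/cm2); negative = depolarizing at rest for an
#'   excitatory synapse
#' @examples
#' synaptic_current(-65, 0)  # 0.05 * 1 * (-65 - 0) = -3.25
#' @export
synaptic_current <- function(V, t_since_event, p = synapse_parameters()) {
  p$gmax * synaptic_release_probability(t_since_event, p) * (V - p$Esyn)
}
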