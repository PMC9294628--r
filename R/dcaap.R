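#' Create a dendritic calcium spike state
#'
#' Tracks whether a dCaAP waveform is in progress, its activation time `t'`,
#' and the amplitude factor K frozen at activation.
#'
#' @param active logical, waveform in progress
#' @param t_prime activation time of the current or most recent dCaAP (ms);
#'   `NA` if the mechanism has never fired
#' @param K_at_activation amplitude factor frozen at activation
#' @return an object of class `dcaap_state`
#' @export
dcaap_state <- function(active = FALSE, t_prime = NA_real_,
                        K_at_activation = 1) {
  stopifnot(K_at_activation > 0, K_at_activation <= 1)
  structure(list(active = active, t_prime = t_prime,
                 K_at_activation = K_at_activation),
            class = "dcaap_state")
}

#' Threshold-and-refractory trigger of the dCaAP
#'
#' If the dendritic voltage is at or above threshold and the mechanism is
#' eligible (never fired, or at least `refractory` ms since the last
#' activation), the dCaAP activates: `t'` is set to the current time and the
#' amplitude factor K = exp(-F (V_dend - V_thresh) / tau_K) is computed from
#' the voltage at this instant and frozen. K decreases with the overshoot
#' above threshold, so stronger drive produces a smaller dCaAP.
#'
#' @param V_dend dendritic membrane voltage (mV)
#' @param t_now current time (ms)
#' @param state [dcaap_state()]
#' @param p [dcaap_parameters()]
#' @return the (possibly updated) `dcaap_state`
#' @examples
#' st <- dcaap_trigger(-36, 0, dcaap_state())
#' st$K_at_activation  # exactly 1 at threshold
#' @export
dcaap_trigger <- function(V_dend, t_now, state = dcaap_state(),
                          p = dcaap_parameters()) {
  stopifnot(inherits(state, "dcaap_state"), inherits(p, "dcaap_parameters"))
  eligible <- is.na(state$t_prime) || (t_now - state$t_prime >= p$refractory)
  if (V_dend >= p$V_thresh && eligible) {
    K <- exp(-p$F_norm * (V_dend - p$V_thresh) / p$tau_K)
    state$active <- TRUE
    state$t_prime <- t_now
    state$K_at_activation <- K
  }
  state
}

#' dCaAP rise/decay waveform
#'
#' A - B with A = 1/(1 + exp(-(t - t')/tau_A)) and
#' B = 1/(1 + exp(-(t - (t' + delta_t'))/tau_B)): a sigmoid rise on tau_A
#' followed, delta_t' later, by a sharp sigmoid cutoff on tau_B. The
#' difference is clamped at zero (in exact arithmetic it becomes negligibly
#' negative once the cutoff sigmoid overtakes the rise, around
#' t - t' = 24 ms with the default constants).
#'
#' @param t_minus_tprime time since activation (ms), non-negative
#' @param p [dcaap_parameters()]
#' @return dimensionless waveform value in \[0, 1)
#' @examples
#' ab_waveform(0)   # ~0.5: rise sigmoid at midpoint, cutoff still closed
#' @export
ab_waveform <- function(t_minus_tprime, p = dcaap_parameters()) {
  if (any(t_minus_tprime < 0)) stop("t_minus_tprime must be non-negative")
  A <- 1 / (1 + exp(-t_minus_tprime / p$tau_A))
  B <- 1 / (1 + exp(-(t_minus_tprime - p$delta_t_prime) / p$tau_B))
  pmax(A - B, 0)
}

#' dCaAP current (dimensionless waveform units)
#'
#' -omega K (A - B) while a waveform is in progress, 0 otherwise. The
#' waveform is considered finished once its raw value falls below 1e-9. The
#' solver converts this dimensionless current into a membrane current
#' density via the `dcaap_scale` geometry parameter.
#'
#' @param state [dcaap_state()]
#' @param t_now current time (ms)
#' @param p [dcaap_parameters()]
#' @return current in waveform units; negative = inward (depolarizing)
#' @export
dcaap_current <- function(state, t_now, p = dcaap_parameters()) {
  stopifnot(inherits(state, "dcaap_state"))
  if (!state$active) return(0)
  elapsed <- t_now - state$t_prime
  if (elapsed < 0) stop("t_now precedes the activation time")
  A <- 1 / (1 + exp(-elapsed / p$tau_A))
  B <- 1 / (1 + exp(-(elapsed - p$delta_t_prime) / p$tau_B))
  raw <- A - B
  if (raw < 1e-9) return(0)
  -p$omega * state$K_at_activation * raw
}

#' Total dendritic membrane current density
#'
#' Leak plus the dCaAP current: gL (V_dend - EL) + scale * I_dCaAP, in
#' uA/cm2.
#'
#' @param V_dend dendritic membrane voltage (mV)
#' @param state [dcaap_state()]
#' @param t_now current time (ms)
#' @param hh [hh_parameters()] (supplies the leak conductance and reversal)
#' @param p [dcaap_parameters()]
#' @param scale current-density scale applied to the dimensionless dCaAP
#'   current (uA/cm2 per unit); 1 leaves the waveform units untouched
#' @return current density (uA/cm2); positive = outward
#' @export
dendritic_membrane_current <- function(V_dend, state, t_now,
                                       hh = hh_parameters(),
                                       p = dcaap_parameters(),
                                       scale = 1) {
  1000 * hh$gL * (V_dend - hh$EL) + scale * dcaap_current(state, t_now, p)
}
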