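#' Define a stimulus protocol
#'
#' A protocol is the full description of one simulation run: duration and
#' timestep, per-compartment injected current waveforms (nA), and
#' per-compartment synaptic event trains. A settling period with no stimulus
#' precedes stimulus onset so that runs start from the model's numerical
#' resting state; time 0 is stimulus onset and the settling window is not
#' recorded.
#'
#' @param duration stimulus duration (ms); must be a multiple of `dt`
#' @param dt timestep (ms)
#' @param settle settling time before stimulus onset (ms)
#' @param ie_soma,ie_dend injected current into each compartment: a scalar
#'   (constant nA), a numeric vector with one value per step, or a function
#'   of time `f(t)` returning nA (evaluated at the end of each step)
#' @param syn_soma,syn_dend synaptic event trains: a list with one numeric
#'   vector of presynaptic event times (ms in \[0, duration\]) per synapse
#' @return an object of class `stimulus_protocol`
#' @examples
#' stimulus_protocol(2000, ie_soma = 0.3)
#' stimulus_protocol(500, syn_dend = rep(list(seq(0, 450, by = 50)), 10))
#' @export
stimulus_protocol <- function(duration, dt = 0.1, settle = 100,
                              ie_soma = 0, ie_dend = 0,
                              syn_soma = list(), syn_dend = list()) {
  if (dt <= 0) stop("dt must be positive")
  n <- duration / dt
  if (abs(n - round(n)) > 1e-9) stop("duration must be a multiple of dt")
  n <- round(n)
  check_events <- function(l, what) {
    if (!is.list(l)) stop(what, " must be a list of event-time vectors")
    for (ev in l) {
      if (length(ev) && (any(ev < 0) || any(ev > duration)))
        stop(what, " event times must lie within [0, duration]")
      if (is.unsorted(ev)) stop(what, " event times must be sorted")
    }
  }
  check_events(syn_soma, "syn_soma"); check_events(syn_dend, "syn_dend")
  structure(list(duration = duration, dt = dt, settle = settle,
                 n_steps = n, ie_soma = ie_soma, ie_dend = ie_dend,
                 syn_soma = syn_soma, syn_dend = syn_dend),
            class = "stimulus_protocol")
}

# expand an ie specification to one nA value per step (value k applies over
# the step ending at k*dt)
expand_ie <- function(ie, n, dt) {
  if (is.function(ie)) return(vapply(seq_len(n) * dt, ie, numeric(1)))
  if (length(ie) == 1) return(rep(as.numeric(ie), n))
  if (length(ie) != n) stop("ie vector must have one value per step")
  as.numeric(ie)
}

# default initial state: -65 mV, gates at their -65 mV equilibrium, dCaAP
# inactive and eligible, all synapses unactivated
default_init_state <- function(protocol) {
  eq <- gating_equilibrium(-65)
  list(v_soma = -65, v_dend = -65,
       m = eq$m_inf, h = eq$h_inf, n = eq$n_inf,
       dcaap_active = FALSE, dcaap_fired = FALSE,
       dcaap_tprime_step = 0L, dcaap_K = 1,
       ps_soma = rep(0, length(protocol$syn_soma)),
       ps_dend = rep(0, length(protocol$syn_dend)))
}

build_cfg <- function(model, protocol, params, arithmetic, gating, lut_step,
                      record_gates, record_idcaap, init_state) {
  dt <- protocol$dt
  n <- protocol$n_steps
  hh <- params$hh; dc <- params$dcaap; sy <- params$synapse
  ge <- params$geometry
  cpar <- list(
    gna = 1000 * hh$gNa, gk = 1000 * hh$gK, gl = 1000 * hh$gL,
    ena = hh$ENa, ek = hh$EK, el = hh$EL, cm = hh$Cm,
    g_ds = ge$g_ds, g_sd = ge$g_sd,
    esyn = sy$Esyn, taus = sy$tau_s, pmax = sy$Pmax,
    vth = dc$V_thresh, fdivtau = dc$F_norm / dc$tau_K,
    omega_scale = dc$omega * ge$dcaap_scale,
    tauA = dc$tau_A, tauB = dc$tau_B, dtprime = dc$delta_t_prime,
    refrac_steps = as.integer(round(dc$refractory / dt)),
    ab_eps = 1e-9)
  mk_syn <- function(evlist) {
    lapply(evlist, function(ev) {
      list(gmax = sy$gmax, steps = as.integer(floor(ev / dt) + 1L))
    })
  }
  lut <- NULL; ab <- NULL
  if (gating == "lut") {
    tab <- build_gating_tables(-100, 100, lut_step, dt)
    lut <- list(vmin = attr(tab, "Vmin"), step = attr(tab, "step"),
                n_inf = tab$n_inf, m_inf = tab$m_inf, h_inf = tab$h_inf,
                expfac_n = tab$expfac_n, expfac_m = tab$expfac_m,
                expfac_h = tab$expfac_h)
    if (model == 2) ab <- build_ab_table(dt, dc)$ab
  }
  list(model = as.integer(model), fixed = (arithmetic == "fixed"),
       use_lut = (gating == "lut"), dt = dt, params = cpar,
       n_settle = as.integer(round(protocol$settle / dt)),
       n_steps = as.integer(n),
       ie_soma = 0.1 * expand_ie(protocol$ie_soma, n, dt) / ge$A_soma,
       ie_dend = 0.1 * expand_ie(protocol$ie_dend, n, dt) / ge$A_dend,
       syn_soma = mk_syn(protocol$syn_soma),
       syn_dend = mk_syn(protocol$syn_dend),
       lut = lut, ab_lut = ab,
       record_gates = record_gates, record_idcaap = record_idcaap,
       init_state = init_state)
}

#' Simulate a neuron under a stimulus protocol
#'
#' Runs the single-compartment HH soma or the two-compartment soma+dendrite
#' (dCaAP) model. Each step applies, in order: synaptic events and release
#' decay; gating advance from the pre-step somatic voltage (closed-form
#' exponential update); dCaAP trigger evaluation on the pre-step dendritic
#' voltage; and a backward-Euler voltage update that is linear in voltage
#' given the updated states (a joint 2x2 solve for the coupled model).
#' Somatic spikes are upward crossings of `threshold` with hysteresis.
#' Everything is deterministic: identical configurations produce identical
#' results, bit for bit.
#'
#' @param protocol a [stimulus_protocol()]
#' @param model `"single"` (HH soma only) or `"two"` (soma + dCaAP dendrite)
#' @param params [neuron_parameters()]
#' @param arithmetic `"double"` (IEEE double precision) or `"fixed"`
#'   (emulated s16.15/u0.32 with round-to-nearest and saturation)
#' @param gating `"direct"` (rate functions evaluated each step) or `"lut"`
#'   (voltage-indexed gating tables and time-indexed dCaAP waveform table)
#' @param lut_step voltage grid spacing of the gating tables (mV)
#' @param record_gates record m/h/n traces
#' @param record_idcaap record the dCaAP current-density trace
#' @param threshold spike detection threshold (mV)
#' @param init optional initial state (as returned in `$final_state`)
#' @return an object of class `neuron_sim` with elements `time` (ms),
#'   `v_soma`, `v_dend` (mV), `spikes_soma` (ms), `dcaap_onsets` (ms),
#'   `dcaap_K`, optional `gates` and `i_dcaap`, `sat_count`, `final_state`,
#'   and `meta`
#' @examples
#' sim <- simulate_neuron(stimulus_protocol(200, ie_soma = 3))
#' length(sim$spikes_soma)
#' @export
simulate_neuron <- function(protocol,
                            model = c("single", "two"),
                            params = neuron_parameters(),
                            arithmetic = c("double", "fixed"),
                            gating = c("direct", "lut"),
                            lut_step = 1,
                            record_gates = FALSE,
                            record_idcaap = (model == "two"),
                            threshold = -20,
                            init = NULL) {
  model <- match.arg(model)
  arithmetic <- match.arg(arithmetic)
  gating <- match.arg(gating)
  force(record_idcaap)
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(params, "neuron_parameters"))
  mnum <- if (model == "two") 2L else 1L
  init_state <- if (is.null(init)) default_init_state(protocol) else init
  cfg <- build_cfg(mnum, protocol, params, arithmetic, gating, lut_step,
                   record_gates, record_idcaap && mnum == 2L, init_state)
  out <- cpp_simulate(cfg)
  time <- protocol$dt * (0:protocol$n_steps)
  res <- list(
    time = time,
    v_soma = out$v_soma,
    v_dend = if (mnum == 2L) out$v_dend else NULL,
    spikes_soma = detect_spikes(out$v_soma, protocol$dt, threshold),
    dcaap_onsets = out$dcaap_onsets,
    dcaap_K = out$dcaap_K,
    gates = if (record_gates)
      data.frame(m = out$m, h = out$h, n = out$n) else NULL,
    i_dcaap = if (record_idcaap && mnum == 2L) out$i_dcaap else NULL,
    sat_count = out$sat_count,
    final_state = out$final_state,
    protocol = protocol,
    meta = list(model = model, arithmetic = arithmetic, gating = gating,
                lut_step = if (gating == "lut") lut_step else NA_real_,
                dt = protocol$dt, duration = protocol$duration,
                settle = protocol$settle, threshold = threshold))
  class(res) <- "neuron_sim"
  res
}

#' Detect spikes by threshold crossing with hysteresis
#'
#' A spike is recorded at each sample where the voltage crosses `threshold`
#' upward; after a detection no new spike is recorded until the voltage has
#' fallen back below the threshold, so a plateau above threshold counts
#' once.
#'
#' @param v voltage trace (mV); sample i corresponds to time (i-1)*dt
#' @param dt sampling interval (ms)
#' @param threshold detection threshold (mV)
#' @return spike times (ms), possibly empty
#' @examples
#' detect_spikes(c(-65, -30, -10, -10, -40), dt = 0.1)  # one spike at 0.1
#' @export
detect_spikes <- function(v, dt = 0.1, threshold = -20) {
  if (!length(v)) stop("empty voltage trace")
  above <- v >= threshold
  rising <- which(above & !c(TRUE, above[-length(above)]))
  dt * (rising - 1)
}

#' Advance the single-compartment model by one step
#'
#' One backward-Euler step of the HH soma: the gates are advanced first with
#' the pre-step voltage, then the membrane equation - linear in voltage
#' given the updated gates - is solved in closed form. Unconditionally
#' stable for any dt.
#'
#' @param state list with elements `V` (mV) and gates `m`, `h`, `n`
#' @param Ie injected current (nA)
#' @param dt timestep (ms)
#' @param params [neuron_parameters()]
#' @param arithmetic,gating,lut_step as in [simulate_neuron()]
#' @return the updated state list
#' @examples
#' eq <- gating_equilibrium(-65)
#' step_single(list(V = -65, m = eq$m_inf, h = eq$h_inf, n = eq$n_inf), 0)
#' @export
step_single <- function(state, Ie, dt = 0.1, params = neuron_parameters(),
                        arithmetic = c("double", "fixed"),
                        gating = c("direct", "lut"), lut_step = 1) {
  arithmetic <- match.arg(arithmetic); gating <- match.arg(gating)
  prot <- stimulus_protocol(dt, dt = dt, settle = 0, ie_soma = Ie)
  init <- default_init_state(prot)
  init$v_soma <- state$V; init$m <- state$m; init$h <- state$h
  init$n <- state$n
  cfg <- build_cfg(1L, prot, params, arithmetic, gating, lut_step,
                   FALSE, FALSE, init)
  out <- cpp_simulate(cfg)
  fs <- out$final_state
  list(V = fs$v_soma, m = fs$m, h = fs$h, n = fs$n)
}

#' Advance the two-compartment model by one step
#'
#' Somatic gates are advanced with the pre-step somatic voltage; the dCaAP
#' trigger is evaluated on the pre-step dendritic voltage; both voltages are
#' then advanced simultaneously by solving the 2x2 linear system of the
#' backward-Euler discretization with coupling currents g (V_other -
#' V_self). With both couplings zero each compartment's update equals the
#' corresponding uncoupled single-compartment update exactly.
#'
#' @param soma list with elements `V`, `m`, `h`, `n`
#' @param dend list with elements `V` and optionally `dcaap` (a
#'   [dcaap_state()])
#' @param Ie_s,Ie_d injected currents (nA)
#' @param t_now current time (ms); activation times in `dend$dcaap` are
#'   interpreted relative to this
#' @inheritParams step_single
#' @return list with updated `soma` and `dend` state lists
#' @export
step_two <- function(soma, dend, Ie_s = 0, Ie_d = 0, t_now = 0, dt = 0.1,
                     params = neuron_parameters(),
                     arithmetic = c("double", "fixed"),
                     gating = c("direct", "lut"), lut_step = 1) {
  arithmetic <- match.arg(arithmetic); gating <- match.arg(gating)
  prot <- stimulus_protocol(dt, dt = dt, settle = 0,
                            ie_soma = Ie_s, ie_dend = Ie_d)
  init <- default_init_state(prot)
  init$v_soma <- soma$V; init$m <- soma$m; init$h <- soma$h; init$n <- soma$n
  init$v_dend <- dend$V
  dc <- if (!is.null(dend$dcaap)) dend$dcaap else dcaap_state()
  init$dcaap_active <- isTRUE(dc$active)
  init$dcaap_fired <- !is.na(dc$t_prime)
  init$dcaap_tprime_step <- if (is.na(dc$t_prime)) 0L else
    as.integer(round((dc$t_prime - t_now) / dt))
  init$dcaap_K <- dc$K_at_activation
  cfg <- build_cfg(2L, prot, params, arithmetic, gating, lut_step,
                   FALSE, FALSE, init)
  out <- cpp_simulate(cfg)
  fs <- out$final_state
  tp <- if (fs$dcaap_fired) t_now + dt * fs$dcaap_tprime_step else NA_real_
  list(soma = list(V = fs$v_soma, m = fs$m, h = fs$h, n = fs$n),
       dend = list(V = fs$v_dend,
                   dcaap = dcaap_state(active = fs$dcaap_active,
                                       t_prime = tp,
                                       K_at_activation = max(fs$dcaap_K,
                                                             1e-12))))
}
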