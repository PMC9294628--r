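# Cross-arithmetic validation harness: trace comparison, current sweeps,
# LUT-resolution study.

#' Compare two simulation results
#'
#' Pointwise maximum absolute voltage error per compartment and ordered
#' spike-time deltas (k-th spike paired with k-th spike; unequal counts set
#' the mismatch flag and unpaired spikes are excluded from the deltas).
#'
#' @param a,b `neuron_sim` objects from identical protocols (same time grid)
#' @return an object of class `trace_comparison` with elements
#'   `max_abs_error` (named per compartment, mV), `spike_deltas` (ms),
#'   `dcaap_deltas` (ms, two-compartment only), `count_mismatch`, `meta`
#' @examples
#' \donttest{
#' p <- stimulus_protocol(500, ie_soma = 3)
#' a <- simulate_neuron(p)
#' b <- simulate_neuron(p, arithmetic = "fixed", gating = "lut")
#' compare_traces(a, b)
#' }
#' @export
compare_traces <- function(a, b) {
  stopifnot(inherits(a, "neuron_sim"), inherits(b, "neuron_sim"))
  if (length(a$time) != length(b$time) ||
      !isTRUE(all.equal(a$time, b$time)))
    stop("simulations are on different time grids and cannot be compared")
  err <- c(soma = max(abs(a$v_soma - b$v_soma)))
  if (!is.null(a$v_dend) && !is.null(b$v_dend))
    err["dend"] <- max(abs(a$v_dend - b$v_dend))
  pair <- function(x, y) {
    k <- min(length(x), length(y))
    if (k == 0) numeric(0) else abs(x[seq_len(k)] - y[seq_len(k)])
  }
  sd_ <- pair(a$spikes_soma, b$spikes_soma)
  dd <- pair(a$dcaap_onsets, b$dcaap_onsets)
  structure(list(
    max_abs_error = err,
    spike_deltas = sd_,
    dcaap_deltas = dd,
    count_mismatch = (length(a$spikes_soma) != length(b$spikes_soma)) ||
      (length(a$dcaap_onsets) != length(b$dcaap_onsets)),
    meta = list(a = a$meta, b = b$meta)),
    class = "trace_comparison")
}

#' @export
print.trace_comparison <- function(x, ...) {
  cat(sprintf("Trace comparison (%s/%s vs %s/%s)\n",
              x$meta$a$arithmetic, x$meta$a$gating,
              x$meta$b$arithmetic, x$meta$b$gating))
  for (nm in names(x$max_abs_error))
    cat(sprintf("  max |dV| %s: %.6g mV\n", nm, x$max_abs_error[[nm]]))
  if (length(x$spike_deltas))
    cat(sprintf("  spike-time deltas: max %.3g ms over %d matched spikes\n",
                max(x$spike_deltas), length(x$spike_deltas)))
  else cat("  no matched spikes\n")
  if (x$count_mismatch) cat("  WARNING: spike-count mismatch\n")
  invisible(x)
}

#' Current sweep comparison between arithmetic/gating modes
#'
#' Runs constant current injections over a range (the published methodology
#' uses 0-10 nA for 2 s each) in two simulation modes and compares traces
#' and spike times at every current.
#'
#' @param currents injected currents (nA)
#' @param duration per-current simulation time (ms)
#' @param model `"single"` or `"two"`
#' @param target `"soma"` or `"dend"`: which compartment receives the
#'   current
#' @param mode_a,mode_b lists with elements `arithmetic`, `gating` and
#'   optionally `lut_step`. The default compares the emulated fixed-point
#'   lookup-table implementation against a double-precision reference with
#'   the same gating path, mirroring how the original benchmarking
#'   configured its reference simulator (whose standard Hodgkin-Huxley
#'   mechanism also tabulates the gating functions at 1 mV); with matched
#'   gating paths the comparison isolates the arithmetic error
#' @param params [neuron_parameters()]
#' @param dt timestep (ms)
#' @return an object of class `sweep_report`: a data.frame with one row per
#'   current (`current`, `max_abs_error`, `max_spike_delta`, `n_spikes_a`,
#'   `n_spikes_b`, `count_mismatch`) with sweep metadata in attributes
#' @examples
#' \donttest{
#' current_sweep(currents = c(0, 3), duration = 500)
#' }
#' @export
current_sweep <- function(currents = seq(0, 10, by = 0.5), duration = 2000,
                          model = "single", target = c("soma", "dend"),
                          mode_a = list(arithmetic = "fixed", gating = "lut",
                                        lut_step = 1),
                          mode_b = list(arithmetic = "double",
                                        gating = "lut", lut_step = 1),
                          params = neuron_parameters(), dt = 0.1) {
  target <- match.arg(target)
  if (target == "dend" && model != "two")
    stop("dendritic injection requires the two-compartment model")
  run_mode <- function(prot, mode)
    simulate_neuron(prot, model = model, params = params,
                    arithmetic = mode$arithmetic, gating = mode$gating,
                    lut_step = if (is.null(mode$lut_step)) 1 else mode$lut_step)
  rows <- lapply(currents, function(i) {
    prot <- if (target == "soma")
      stimulus_protocol(duration, dt = dt, ie_soma = i)
    else stimulus_protocol(duration, dt = dt, ie_dend = i)
    a <- run_mode(prot, mode_a)
    b <- run_mode(prot, mode_b)
    cmp <- compare_traces(a, b)
    data.frame(current = i,
               max_abs_error = max(cmp$max_abs_error),
               max_spike_delta = if (length(cmp$spike_deltas))
                 max(cmp$spike_deltas) else 0,
               n_spikes_a = length(a$spikes_soma),
               n_spikes_b = length(b$spikes_soma),
               count_mismatch = cmp$count_mismatch)
  })
  res <- do.call(rbind, rows)
  attr(res, "mode_a") <- mode_a
  attr(res, "mode_b") <- mode_b
  attr(res, "duration") <- duration
  attr(res, "dt") <- dt
  attr(res, "aggregate_max_error") <- max(res$max_abs_error)
  attr(res, "aggregate_max_spike_delta") <- max(res$max_spike_delta)
  class(res) <- c("sweep_report", "data.frame")
  res
}

#' @export
print.sweep_report <- function(x, ...) {
  ma <- attr(x, "mode_a"); mb <- attr(x, "mode_b")
  cat(sprintf("Current sweep: %s+%s vs %s+%s, %d currents, %g ms each\n",
              ma$arithmetic, ma$gating, mb$arithmetic, mb$gating,
              nrow(x), attr(x, "duration")))
  cat(sprintf("  aggregate max |dV|: %.4g mV\n",
              attr(x, "aggregate_max_error")))
  cat(sprintf("  aggregate max spike-time delta: %.3g ms\n",
              attr(x, "aggregate_max_spike_delta")))
  if (any(x$count_mismatch))
    cat(sprintf("  spike-count mismatches at: %s nA\n",
                paste(x$current[x$count_mismatch], collapse = ", ")))
  invisible(x)
}

#' Lookup-table resolution study
#'
#' Simulates one protocol in a chosen arithmetic mode with direct gating
#' evaluation ("no LUT") and with gating tables of the given voltage
#' resolutions, and reports each variant's whole-run maximum voltage error
#' against the double-precision direct-evaluation reference.
#'
#' @param current somatic current (nA)
#' @param duration simulation time (ms)
#' @param arithmetic arithmetic mode of the variants under study
#' @param lut_steps table resolutions to test (mV)
#' @param params [neuron_parameters()]
#' @return a data.frame with columns `variant`, `lut_step`,
#'   `max_abs_error`, `n_spikes`, `max_spike_delta`
#' @examples
#' \donttest{
#' lut_resolution_study(duration = 500)
#' }
#' @export
lut_resolution_study <- function(current = 3, duration = 2000,
                                 arithmetic = "fixed", lut_steps = c(2, 1),
                                 params = neuron_parameters()) {
  prot <- stimulus_protocol(duration, ie_soma = current)
  ref <- simulate_neuron(prot, params = params, arithmetic = "double",
                         gating = "direct")
  variants <- c(list(list(label = "no-LUT", gating = "direct", step = NA)),
                lapply(lut_steps, function(s)
                  list(label = sprintf("%g mV LUT", s), gating = "lut",
                       step = s)))
  rows <- lapply(variants, function(v) {
    s <- simulate_neuron(prot, params = params, arithmetic = arithmetic,
                         gating = v$gating,
                         lut_step = if (is.na(v$step)) 1 else v$step)
    cmp <- compare_traces(s, ref)
    data.frame(variant = v$label, lut_step = v$step,
               max_abs_error = max(cmp$max_abs_error),
               n_spikes = length(s$spikes_soma),
               max_spike_delta = if (length(cmp$spike_deltas))
                 max(cmp$spike_deltas) else 0)
  })
  do.call(rbind, rows)
}

#' Serialize a comparison or sweep report as structured text
#'
#' One record per entry in a plain key/value text layout, reproducible byte
#' for byte for identical runs.
#'
#' @param x a `trace_comparison` or `sweep_report`
#' @param file destination path
#' @return `file`, invisibly
#' @export
write_report <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(x, "trace_comparison")) {
    writeLines("record: trace_comparison", con)
    for (nm in names(x$max_abs_error))
      writeLines(sprintf("max_abs_error_%s: %.10g", nm,
                         x$max_abs_error[[nm]]), con)
    writeLines(sprintf("spike_deltas: %s",
                       paste(sprintf("%.10g", x$spike_deltas),
                             collapse = " ")), con)
    writeLines(sprintf("count_mismatch: %s", x$count_mismatch), con)
  } else if (inherits(x, "sweep_report")) {
    writeLines("record: sweep_report", con)
    writeLines(sprintf("aggregate_max_error: %.10g",
                       attr(x, "aggregate_max_error")), con)
    writeLines(sprintf("aggregate_max_spike_delta: %.10g",
                       attr(x, "aggregate_max_spike_delta")), con)
    for (i in seq_len(nrow(x)))
      writeLines(sprintf(
        "current: %.10g max_abs_error: %.10g max_spike_delta: %.10g mismatch: %s",
        x$current[i], x$max_abs_error[i], x$max_spike_delta[i],
        x$count_mismatch[i]), con)
  } else stop("unsupported report type")
  invisible(file)
}

#' Per-dCaAP-window dendritic error analysis
#'
#' Splits the dendritic voltage error between two simulations into the
#' windows covered by successive dCaAP waveforms (onset to onset + 25 ms,
#' the waveform support) and the refractory gaps between them. Because the
#' dCaAP current drops to exactly zero after each waveform, errors do not
#' accumulate across waveforms: between windows the dendrite is passive and
#' the error collapses to the arithmetic rounding floor.
#'
#' @param a,b `neuron_sim` objects from identical two-compartment protocols
#' @param support waveform window length after each onset (ms)
#' @return a list with `window_max` (max |dV_dend| per dCaAP window),
#'   `between_max` (max error outside all windows) and `onsets`
#' @export
dcaap_window_errors <- function(a, b, support = 25) {
  stopifnot(!is.null(a$v_dend), !is.null(b$v_dend))
  if (length(a$time) != length(b$time))
    stop("simulations are on different time grids")
  err <- abs(a$v_dend - b$v_dend)
  onsets <- a$dcaap_onsets
  inwin <- rep(FALSE, length(err))
  wmax <- numeric(length(onsets))
  for (k in seq_along(onsets)) {
    w <- a$time >= onsets[k] & a$time <= onsets[k] + support
    inwin <- inwin | w
    wmax[k] <- if (any(w)) max(err[w]) else 0
  }
  list(window_max = wmax,
       between_max = if (any(!inwin)) max(err[!inwin]) else 0,
       onsets = onsets)
}
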