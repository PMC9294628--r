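#' @export
print.neuron_sim <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<neuron_sim: %s-compartment, %s arithmetic, %s gating%s>\n",
              m$model, m$arithmetic, m$gating,
              if (!is.na(m$lut_step)) sprintf(" (%g mV)", m$lut_step) else ""))
  cat(sprintf("  %g ms at dt = %g ms (%d samples), %g ms settling\n",
              m$duration, m$dt, length(x$time), m$settle))
  cat(sprintf("  somatic spikes: %d", length(x$spikes_soma)))
  if (length(x$spikes_soma))
    cat(sprintf(" (first at %.1f ms)", x$spikes_soma[1]))
  cat("\n")
  if (m$model == "two")
    cat(sprintf("  dCaAP onsets: %d\n", length(x$dcaap_onsets)))
  if (x$sat_count > 0)
    cat(sprintf("  fixed-point saturation events: %g\n", x$sat_count))
  invisible(x)
}

#' @export
summary.neuron_sim <- function(object, ...) {
  x <- object
  sp <- x$spikes_soma
  isi <- diff(sp)
  out <- list(
    model = x$meta$model,
    arithmetic = x$meta$arithmetic,
    gating = x$meta$gating,
    n_spikes = length(sp),
    first_spike = if (length(sp)) sp[1] else NA_real_,
    mean_rate_hz = if (x$meta$duration > 0)
      1000 * length(sp) / x$meta$duration else NA_real_,
    isi_mean = if (length(isi)) mean(isi) else NA_real_,
    isi_cv = if (length(isi) > 1) stats::sd(isi) / mean(isi) else NA_real_,
    v_soma_range = range(x$v_soma),
    n_dcaap = length(x$dcaap_onsets),
    dcaap_K = x$dcaap_K,
    sat_count = x$sat_count)
  class(out) <- "summary.neuron_sim"
  out
}

#' @export
print.summary.neuron_sim <- function(x, ...) {
  cat(sprintf("%s-compartment simulation (%s, %s)\n",
              x$model, x$arithmetic, x$gating))
  cat(sprintf("  somatic spikes: %d (mean rate %.1f Hz)\n",
              x$n_spikes, x$mean_rate_hz))
  if (!is.na(x$isi_mean))
    cat(sprintf("  mean ISI %.2f ms, CV %.3f\n", x$isi_mean,
                ifelse(is.na(x$isi_cv), 0, x$isi_cv)))
  cat(sprintf("  somatic voltage range [%.1f, %.1f] mV\n",
              x$v_soma_range[1], x$v_soma_range[2]))
  if (x$n_dcaap > 0)
    cat(sprintf("  dCaAPs: %d, amplitude factors K = %s\n", x$n_dcaap,
                paste(sprintf("%.3f", x$dcaap_K), collapse = ", ")))
  invisible(x)
}

#' Plot simulated membrane potential traces
#'
#' Somatic (and, for the two-compartment model, dendritic) voltage against
#' time, with detected spikes and dCaAP onsets marked.
#'
#' @param x a `neuron_sim`
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.neuron_sim <- function(x, ...) {
  two <- !is.null(x$v_dend)
  if (two) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
  }
  graphics::plot(x$time, x$v_soma, type = "l", xlab = "time (ms)",
                 ylab = "V_soma (mV)", ...)
  if (length(x$spikes_soma))
    graphics::points(x$spikes_soma,
                     rep(max(x$v_soma) + 2, length(x$spikes_soma)),
                     pch = "|", col = "red3")
  if (two) {
    graphics::plot(x$time, x$v_dend, type = "l", xlab = "time (ms)",
                   ylab = "V_dend (mV)")
    if (length(x$dcaap_onsets))
      graphics::abline(v = x$dcaap_onsets, lty = 3, col = "blue3")
  }
  invisible(x)
}
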