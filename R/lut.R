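#' Build the voltage-indexed gating lookup table
#'
#' Pre-computes, on a regular voltage grid, the gating equilibria n_inf,
#' m_inf, h_inf and the per-step decay factors exp(-dt/tau_x) for each gate,
#' so that a state update reduces to table lookups followed by one
#' multiplication and addition per gate. The decay factor is stored with the
#' stable negative exponent (exp(-dt/tau); the positive sign would diverge).
#'
#' @param Vmin,Vmax grid bounds (mV)
#' @param step grid spacing (mV); (Vmax - Vmin)/step must be integral
#' @param dt the timestep the table is built for (ms)
#' @return an object of class `gating_lut`: a data.frame with columns `V`,
#'   `n_inf`, `m_inf`, `h_inf`, `expfac_n`, `expfac_m`, `expfac_h` and
#'   attributes `Vmin`, `Vmax`, `step`, `dt`, `interpolation`
#' @examples
#' tab <- build_gating_tables()
#' nrow(tab)  # 201 nodes for -100..100 mV at 1 mV
#' @export
build_gating_tables <- function(Vmin = -100, Vmax = 100, step = 1, dt = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (Vmin >= Vmax) stop("Vmin must be below Vmax")
  n <- (Vmax - Vmin) / step
  if (abs(n - round(n)) > 1e-9) stop("(Vmax - Vmin)/step must be integral")
  V <- Vmin + step * 0:round(n)
  eq <- gating_equilibrium(V)
  tab <- data.frame(V = V,
                    n_inf = eq$n_inf, m_inf = eq$m_inf, h_inf = eq$h_inf,
                    expfac_n = exp(-dt / eq$tau_n),
                    expfac_m = exp(-dt / eq$tau_m),
                    expfac_h = exp(-dt / eq$tau_h))
  structure(tab, Vmin = Vmin, Vmax = Vmax, step = step, dt = dt,
            interpolation = "linear", class = c("gating_lut", "data.frame"))
}

#' Query a lookup table
#'
#' Linear interpolation between the bracketing grid nodes; queries outside
#' the grid clamp to the nearest endpoint.
#'
#' @param table a `gating_lut` (or any data.frame whose first column is the
#'   abscissa and whose attributes carry `Vmin`, `Vmax`, `step`)
#' @param x query point(s)
#' @return a data.frame of interpolated column values, one row per query
#' @examples
#' tab <- build_gating_tables()
#' lut_lookup(tab, -64.5)
#' @export
lut_lookup <- function(table, x) {
  vmin <- attr(table, "Vmin"); step <- attr(table, "step")
  n <- nrow(table)
  pos <- (x - vmin) / step
  pos <- pmin(pmax(pos, 0), n - 1)
  i <- pmin(floor(pos), n - 2)
  frac <- pos - i
  cols <- setdiff(names(table), names(table)[1])
  out <- lapply(cols, function(cn) {
    lo <- table[[cn]][i + 1]
    hi <- table[[cn]][i + 2]
    lo + frac * (hi - lo)
  })
  names(out) <- cols
  as.data.frame(out)
}

#' Build the time-indexed dCaAP waveform table
#'
#' Tabulates the A - B rise/decay waveform at `dt_res` resolution from
#' t - t' = 0, truncated at the first node where the value falls below 1e-6
#' (the waveform is treated as 0 beyond). Because t - t' is always an exact
#' multiple of the timestep, this table is queried by nearest node - a single
#' lookup, with no interpolation arithmetic.
#'
#' @param dt_res table resolution (ms), normally the simulation timestep
#' @param p [dcaap_parameters()]
#' @return an object of class `ab_lut`: a data.frame with columns `t` and
#'   `ab`, with attributes `dt_res` and `interpolation = "nearest"`
#' @examples
#' tab <- build_ab_table()
#' tab$ab[1]  # ~0.5 at t - t' = 0
#' @export
build_ab_table <- function(dt_res = 0.1, p = dcaap_parameters()) {
  if (dt_res <= 0) stop("dt_res must be positive")
  # generous upper bound on support; truncated below
  t <- seq(0, 4 * p$delta_t_prime + 20 * p$tau_A, by = dt_res)
  A <- 1 / (1 + exp(-t / p$tau_A))
  B <- 1 / (1 + exp(-(t - p$delta_t_prime) / p$tau_B))
  v <- A - B
  cut <- which(v < 1e-6)[1]
  if (!is.na(cut)) { t <- t[seq_len(cut - 1)]; v <- v[seq_len(cut - 1)] }
  structure(data.frame(t = t, ab = pmax(v, 0)),
            dt_res = dt_res, interpolation = "nearest",
            class = c("ab_lut", "data.frame"))
}

#' One gating update through the lookup table
#'
#' x' = x_inf + (x - x_inf) expfac_x with x_inf and expfac_x interpolated
#' from the table at the given voltage. At a table node this is identical to
#' [advance_gate()].
#'
#' @param gates list with elements `m`, `h`, `n`
#' @param V membrane voltage (mV)
#' @param table a [build_gating_tables()] table
#' @param dt timestep (ms); must equal the dt the table was built with
#' @return the updated gates list
#' @export
gated_step_with_lut <- function(gates, V, table, dt = attr(table, "dt")) {
  if (!isTRUE(all.equal(dt, attr(table, "dt"))))
    stop("dt does not match the dt the table was built with")
  q <- lut_lookup(table, V)
  list(m = q$m_inf + (gates$m - q$m_inf) * q$expfac_m,
       h = q$h_inf + (gates$h - q$h_inf) * q$expfac_h,
       n = q$n_inf + (gates$n - q$n_inf) * q$expfac_n)
}

#' Write / read a lookup table as columnar text
#'
#' One header line naming the columns, one grid node per row; attributes are
#' stored in comment lines, so a written table round-trips through
#' [read_lut()].
#'
#' @param table a `gating_lut` or `ab_lut`
#' @param file path to write to / read from
#' @return `write_lut` returns `file` invisibly; `read_lut` returns the
#'   table with its attributes restored
#' @export
write_lut <- function(table, file) {
  at <- attributes(table)
  meta <- at[setdiff(names(at), c("names", "row.names", "class"))]
  hdr <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                character(1))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_lut
#' @export
read_lut <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^# ", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^# ", lines)], header = TRUE,
                           sep = "\t")
  for (ml in meta_lines) {
    key <- sub("^# ([^:]+): .*$", "\\1", ml)
    val <- sub("^# [^:]+: (.*)$", "\\1", ml)
    num <- suppressWarnings(as.numeric(val))
    attr(tab, key) <- if (is.na(num)) val else num
  }
  cls <- if ("ab" %in% names(tab)) "ab_lut" else "gating_lut"
  class(tab) <- c(cls, "data.frame")
  tab
}
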