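#' Fixed-point number formats
#'
#' The two 32-bit formats used on FPU-less neuromorphic cores:
#' \describe{
#'   \item{`"s16.15"` (accum)}{signed, 16 integer + 15 fractional bits;
#'     representable step 2^-15 ~ 3.05e-5; limits -65536 and
#'     65535.999969482421875. Used for voltages, currents and conductances.}
#'   \item{`"u0.32"` (unsigned long fract)}{unsigned, 32 fractional bits;
#'     values in \[0, 1 - 2^-32\]. Used for quantities confined to \[0, 1):
#'     gates, release probabilities, the dCaAP waveform and amplitude factor,
#'     and the per-step gating decay factors.}
#' }
#' All arithmetic computes an exact wide intermediate, rounds to nearest
#' with ties away from zero, and saturates (rather than wraps) on overflow.
#'
#' @param format `"s16.15"` or `"u0.32"`
#' @return an object of class `fx_format`
#' @examples
#' fx_format("s16.15")
#' @export
fx_format <- function(format = c("s16.15", "u0.32")) {
  format <- match.arg(format)
  if (format == "s16.15")
    structure(list(name = "s16.15", total_bits = 32L, fraction_bits = 15L,
                   signed = TRUE, code = 0L,
                   step = 2^-15, min = -65536, max = 65536 - 2^-15,
                   rounding = "nearest-ties-away", overflow = "saturate"),
              class = "fx_format")
  else
    structure(list(name = "u0.32", total_bits = 32L, fraction_bits = 32L,
                   signed = FALSE, code = 1L,
                   step = 2^-32, min = 0, max = 1 - 2^-32,
                   rounding = "nearest-ties-away", overflow = "saturate"),
              class = "fx_format")
}

#' @export
print.fx_format <- function(x, ...) {
  cat(sprintf("<fx_format %s: %s, %d-bit, %d fraction bits, step %.3g, range [%.12g, %.15g]>\n",
              x$name, if (x$signed) "signed" else "unsigned", x$total_bits,
              x$fraction_bits, x$step, x$min, x$max))
  invisible(x)
}

fmt_of <- function(fmt) {
  if (inherits(fmt, "fx_format")) fmt else fx_format(fmt)
}

#' Quantize real values to a fixed-point format
#'
#' Rounds to the nearest representable value (ties away from zero);
#' out-of-range inputs saturate to the format limits.
#'
#' @param x numeric vector
#' @param fmt an [fx_format()] or format name
#' @return an object of class `fx`: quantized values with their raw integer
#'   payloads
#' @examples
#' quantize(1.5, "s16.15")        # raw 49152
#' quantize(1e6, "s16.15")        # saturates to 65535.999969482421875
#' @export
quantize <- function(x, fmt = "s16.15") {
  fmt <- fmt_of(fmt)
  raw <- cpp_fx_quantize(as.numeric(x), fmt$code)
  new_fx(raw, fmt)
}

new_fx <- function(raw, fmt) {
  structure(list(raw = raw, format = fmt), class = "fx")
}

#' @export
print.fx <- function(x, ...) {
  v <- as.numeric(x)
  cat(sprintf("<fx %s> ", x$format$name))
  cat(format(v, digits = 15), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
as.double.fx <- function(x, ...) cpp_fx_to_double(x$raw, x$format$code)

#' @export
length.fx <- function(x) length(x$raw)

fx_binop <- function(a, b, op) {
  if (!inherits(a, "fx")) a <- quantize(a, b$format)
  if (!inherits(b, "fx")) b <- quantize(b, a$format)
  if (a$format$name != b$format$name) {
    # any mix involving accum is carried out in accum
    acc <- fx_format("s16.15")
    a <- fx_convert(a, acc); b <- fx_convert(b, acc)
  }
  new_fx(cpp_fx_arith(a$raw, b$raw, op, a$format$code), a$format)
}

#' Fixed-point arithmetic
#'
#' Elementwise add/subtract/multiply/divide of fixed-point values: exact
#' wide intermediate, round to nearest (ties away from zero) into the result
#' format, saturate on overflow. Mixing `u0.32` with `s16.15` promotes to
#' `s16.15`. Plain numerics are quantized to the other operand's format
#' first.
#'
#' @param a,b `fx` objects (or numerics)
#' @return an `fx` object
#' @examples
#' fx_mul(quantize(0.5), quantize(0.5))   # exactly 0.25
#' fx_add(quantize(65535), quantize(10))  # saturates at the upper limit
#' @export
fx_add <- function(a, b) fx_binop(a, b, 1L)

#' @rdname fx_add
#' @export
fx_sub <- function(a, b) fx_binop(a, b, 2L)

#' @rdname fx_add
#' @export
fx_mul <- function(a, b) fx_binop(a, b, 3L)

#' @rdname fx_add
#' @export
fx_div <- function(a, b) fx_binop(a, b, 4L)

#' Fixed-point exponential
#'
#' exp evaluated in double precision on the dequantized argument and
#' quantized into the result format (the software-exponential contract of
#' FPU-less cores; the lookup-table path removes runtime exponentials from
#' the simulation loop entirely).
#'
#' @param a an `fx` object
#' @param out_format result format (default: the input's format)
#' @return an `fx` object
#' @examples
#' fx_exp(quantize(1))   # nearest representable to e
#' fx_exp(quantize(12))  # saturates: e^12 > 65536
#' @export
fx_exp <- function(a, out_format = a$format) {
  stopifnot(inherits(a, "fx"))
  out <- fmt_of(out_format)
  new_fx(cpp_fx_exp(a$raw, a$format$code, out$code), out)
}

#' Convert between fixed-point formats
#'
#' Re-rounds the raw payload into the target format (u0.32 -> s16.15 drops
#' 17 fraction bits with round-to-nearest; s16.15 -> u0.32 is exact for
#' values in \[0, 1), saturating outside).
#'
#' @param a an `fx` object
#' @param fmt target [fx_format()]
#' @return an `fx` object
#' @export
fx_convert <- function(a, fmt) {
  fmt <- fmt_of(fmt)
  new_fx(cpp_fx_convert(a$raw, a$format$code, fmt$code), fmt)
}
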