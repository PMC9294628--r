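// R-facing entry points for the emulated fixed-point formats.  Raw payloads
// travel as doubles (all raws are < 2^33, exactly representable).  fmt codes:
// 0 = s16.15 accum (signed), 1 = u0.32 unsigned long fract.

#include <Rcpp.h>
#include "fixed.h"

using namespace Rcpp;

static inline int64_t get_acc(double raw) { return (int64_t)raw; }
static inline uint64_t get_fr(double raw) { return (uint64_t)raw; }

// [[Rcpp::export]]
NumericVector cpp_fx_quantize(NumericVector x, int fmt) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = (fmt == 0) ? (double)fx::acc_from_double(x[i])
                        : (double)fx::fr_from_double(x[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fx_to_double(NumericVector raw, int fmt) {
  NumericVector out(raw.size());
  for (int i = 0; i < raw.size(); ++i)
    out[i] = (fmt == 0) ? fx::acc_to_double(get_acc(raw[i]))
                        : fx::fr_to_double(get_fr(raw[i]));
  return out;
}

// op: 1 add, 2 sub, 3 mul, 4 div
// [[Rcpp::export]]
NumericVector cpp_fx_arith(NumericVector a, NumericVector b, int op, int fmt) {
  int n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (fmt == 0) {
      int64_t x = get_acc(a[i % a.size()]), y = get_acc(b[i % b.size()]);
      int64_t r = 0;
      switch (op) {
        case 1: r = fx::acc_add(x, y); break;
        case 2: r = fx::acc_sub(x, y); break;
        case 3: r = fx::acc_mul(x, y); break;
        case 4:
          if (y == 0) stop("fixed-point division by zero");
          r = fx::acc_div(x, y); break;
      }
      out[i] = (double)r;
    } else {
      uint64_t x = get_fr(a[i % a.size()]), y = get_fr(b[i % b.size()]);
      uint64_t r = 0;
      switch (op) {
        case 1: r = fx::fr_add(x, y); break;
        case 2: r = fx::fr_sub(x, y); break;
        case 3: r = fx::fr_mul(x, y); break;
        case 4:
          if (y == 0) stop("fixed-point division by zero");
          r = fx::fr_div(x, y); break;
      }
      out[i] = (double)r;
    }
  }
  return out;
}

// exp on the dequantized argument, then re-quantized (the software-exp
// contract: the LUT path removes runtime exponentials anyway)
// [[Rcpp::export]]
NumericVector cpp_fx_exp(NumericVector raw, int fmt_in, int fmt_out) {
  NumericVector out(raw.size());
  for (int i = 0; i < raw.size(); ++i) {
    double x = (fmt_in == 0) ? fx::acc_to_double(get_acc(raw[i]))
                             : fx::fr_to_double(get_fr(raw[i]));
    double e = std::exp(x);
    out[i] = (fmt_out == 0) ? (double)fx::acc_from_double(e)
                            : (double)fx::fr_from_double(e);
  }
  return out;
}

// format conversions accum <-> fract on raw payloads
// [[Rcpp::export]]
NumericVector cpp_fx_convert(NumericVector raw, int fmt_in, int fmt_out) {
  NumericVector out(raw.size());
  for (int i = 0; i < raw.size(); ++i) {
    if (fmt_in == fmt_out) out[i] = raw[i];
    else if (fmt_in == 1) out[i] = (double)fx::fr_to_acc(get_fr(raw[i]));
    else out[i] = (double)fx::acc_to_fr(get_acc(raw[i]));
  }
  return out;
}
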