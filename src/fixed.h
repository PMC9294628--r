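// Emulation of the two 32-bit fixed-point formats used on digital
// neuromorphic cores without an FPU:
//   accum : signed s16.15  (16 integer bits + 15 fraction bits + sign)
//   fract : unsigned u0.32 (32 fraction bits, values in [0, 1))
// All operations compute an exact wide intermediate, round to nearest with
// ties away from zero, and saturate on overflow.  Raw payloads are carried
// in 64-bit integers so that R can hold them losslessly in doubles.
#ifndef DENDSPIKE_FIXED_H
#define DENDSPIKE_FIXED_H

#include <cstdint>
#include <cmath>

namespace fx {

constexpr int ACC_FBITS = 15;
constexpr int FR_FBITS  = 32;
constexpr int64_t ACC_MAX = INT64_C(2147483647);   //  65535.999969482421875
constexpr int64_t ACC_MIN = INT64_C(-2147483648);  // -65536
constexpr uint64_t FR_MAX = UINT64_C(4294967295);  // 1 - 2^-32

// saturating accum helpers ---------------------------------------------------
inline int64_t acc_sat(int64_t raw) {
  if (raw > ACC_MAX) return ACC_MAX;
  if (raw < ACC_MIN) return ACC_MIN;
  return raw;
}

inline int64_t acc_from_double(double x) {
  if (std::isnan(x)) return 0;
  double scaled = x * 32768.0;
  if (scaled >= (double)ACC_MAX) return ACC_MAX;
  if (scaled <= (double)ACC_MIN) return ACC_MIN;
  return (int64_t)std::llround(scaled);  // llround: ties away from zero
}

inline double acc_to_double(int64_t raw) { return (double)raw / 32768.0; }

inline int64_t acc_add(int64_t a, int64_t b) { return acc_sat(a + b); }
inline int64_t acc_sub(int64_t a, int64_t b) { return acc_sat(a - b); }

// round-to-nearest, ties away from zero, of (p / 2^shift)
inline int64_t rshift_round(int64_t p, int shift) {
  const int64_t half = INT64_C(1) << (shift - 1);
  if (p >= 0) return (p + half) >> shift;
  return -((-p + half) >> shift);
}

inline int64_t acc_mul(int64_t a, int64_t b) {
  // |a|,|b| <= 2^31 so the product fits in int64 exactly
  return acc_sat(rshift_round(a * b, ACC_FBITS));
}

inline int64_t acc_div(int64_t a, int64_t b) {
  if (b == 0) return (a >= 0) ? ACC_MAX : ACC_MIN;
  __int128 num = ((__int128)a) << ACC_FBITS;
  __int128 q = num / b;              // truncates toward zero
  __int128 r = num - q * b;          // remainder, sign of num
  __int128 b2 = (b >= 0) ? b : -((__int128)b);
  __int128 r2 = (r >= 0) ? r : -r;
  if (2 * r2 >= b2) q += ((num >= 0) == (b >= 0)) ? 1 : -1;
  if (q > ACC_MAX) return ACC_MAX;
  if (q < ACC_MIN) return ACC_MIN;
  return (int64_t)q;
}

// unsigned fract helpers -----------------------------------------------------
inline uint64_t fr_sat(int64_t raw) {
  if (raw < 0) return 0;
  if (raw > (int64_t)FR_MAX) return FR_MAX;
  return (uint64_t)raw;
}

inline uint64_t fr_from_double(double x) {
  if (std::isnan(x) || x <= 0.0) return 0;
  double scaled = x * 4294967296.0;
  if (scaled >= (double)FR_MAX) return FR_MAX;
  return (uint64_t)std::llround(scaled);
}

inline double fr_to_double(uint64_t raw) { return (double)raw / 4294967296.0; }

inline uint64_t fr_add(uint64_t a, uint64_t b) {
  uint64_t s = a + b;
  return (s > FR_MAX) ? FR_MAX : s;
}

inline uint64_t fr_sub(uint64_t a, uint64_t b) { return (a >= b) ? a - b : 0; }

inline uint64_t fr_mul(uint64_t a, uint64_t b) {
  // a,b < 2^32 so a*b fits in uint64; adding the rounding half cannot wrap
  uint64_t p = a * b;
  return (p + (UINT64_C(1) << 31)) >> 32;
}

inline uint64_t fr_div(uint64_t a, uint64_t b) {
  if (b == 0) return FR_MAX;
  unsigned __int128 num = ((unsigned __int128)a) << 32;
  unsigned __int128 q = num / b;
  unsigned __int128 r = num - q * b;
  if (2 * r >= b) q += 1;
  if (q > FR_MAX) return FR_MAX;
  return (uint64_t)q;
}

// conversions ----------------------------------------------------------------
inline int64_t fr_to_acc(uint64_t raw) {
  // 32 -> 15 fraction bits; positive, so ties-away == ties-up
  return (int64_t)((raw + (UINT64_C(1) << 16)) >> 17);
}

inline uint64_t acc_to_fr(int64_t raw) {
  if (raw <= 0) return 0;
  if (raw >= (INT64_C(1) << ACC_FBITS)) return FR_MAX;  // >= 1 saturates
  return ((uint64_t)raw) << 17;                          // exact
}

// accum x fract -> accum (exact 2^63-wide product via __int128)
inline int64_t acc_mul_fr(int64_t a, uint64_t b) {
  __int128 p = (__int128)a * (__int128)b;
  const __int128 half = ((__int128)1) << 31;
  __int128 q = (p >= 0) ? ((p + half) >> 32) : -((-p + half) >> 32);
  if (q > ACC_MAX) return ACC_MAX;
  if (q < ACC_MIN) return ACC_MIN;
  return (int64_t)q;
}

} // namespace fx

#endif
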