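# Emulated s16.15 accum and u0.32 fract arithmetic.

test_that("quantization hits the documented format limits and payloads", {
  expect_equal(quantize(1.5, "s16.15")$raw, 49152)          # 1.5 * 2^15
  expect_equal(quantize(0.5, "u0.32")$raw, 2^31)
  # smallest positive accum value
  expect_equal(as.numeric(quantize(2^-15, "s16.15")), 0.000030517578125)
  expect_equal(as.numeric(quantize(1e-9, "s16.15")), 0)     # below one ulp
  # saturation at the upper limit
  expect_equal(as.numeric(quantize(1e6, "s16.15")), 65535.999969482421875)
  expect_equal(as.numeric(quantize(-1e9, "s16.15")), -65536)
  expect_equal(as.numeric(quantize(2, "u0.32")), 1 - 2^-32)
  expect_equal(as.numeric(quantize(-1, "u0.32")), 0)
})

test_that("arithmetic rounds to nearest with ties away from zero and saturates", {
  # representable product is exact
  expect_equal(as.numeric(fx_mul(quantize(0.5), quantize(0.5))), 0.25)
  # tie: one ulp times 0.5 is half an ulp, rounded away from zero
  expect_equal(fx_mul(quantize(2^-15), quantize(0.5))$raw, 1)
  expect_equal(fx_mul(quantize(-2^-15), quantize(0.5))$raw, -1)
  # saturating addition
  expect_equal(as.numeric(fx_add(quantize(65535), quantize(10))),
               65535.999969482421875)
  expect_error(fx_div(quantize(1), quantize(0)), "zero")
  # division rounds the exact quotient
  expect_equal(as.numeric(fx_div(quantize(1), quantize(3))),
               round((2^15) / 3) / 2^15, tolerance = 1e-12)
})

test_that("integer-arithmetic oracle confirms multiply rounding", {
  set.seed(7)
  # raws kept below 2^26 so the exact products stay inside double precision
  a <- floor(runif(200, 0, 2^26)); b <- floor(runif(200, 0, 2^26))
  got <- fx_mul(structure(list(raw = a, format = fx_format("u0.32")),
                          class = "fx"),
                structure(list(raw = b, format = fx_format("u0.32")),
                          class = "fx"))$raw
  want <- vapply(seq_along(a),
                 function(i) oracle_div_round(a[i] * b[i], 2^32), numeric(1))
  expect_equal(got, want)
  a2 <- floor(runif(200, 0, 2^23)); b2 <- floor(runif(200, 0, 2^23))
  gota <- fx_mul(structure(list(raw = a2, format = fx_format("s16.15")),
                           class = "fx"),
                 structure(list(raw = -b2, format = fx_format("s16.15")),
                           class = "fx"))$raw
  wanta <- vapply(seq_along(a2),
                  function(i) -oracle_div_round(a2[i] * b2[i], 2^15),
                  numeric(1))
  expect_equal(gota, wanta)
})

test_that("round-trip, monotonicity and the multiply error bound hold", {
  set.seed(21)
  for (fmt in c("s16.15", "u0.32")) {
    f <- fx_format(fmt)
    raws <- if (f$signed) floor(runif(300, -2^31, 2^31 - 1))
            else floor(runif(300, 0, 2^32 - 1))
    x <- structure(list(raw = raws, format = f), class = "fx")
    expect_equal(quantize(as.numeric(x), f)$raw, raws)   # round trip
  }
  # monotone: quantization preserves order
  xs <- sort(runif(100, -70000, 70000))
  q <- as.numeric(quantize(xs, "s16.15"))
  expect_true(all(diff(q) >= 0))
  # |fx_mul(a,b) - ab| <= 2^-16 absent saturation
  a <- runif(200, -200, 200); b <- runif(200, -200, 200)
  fa <- quantize(a); fb <- quantize(b)
  err <- abs(as.numeric(fx_mul(fa, fb)) - as.numeric(fa) * as.numeric(fb))
  expect_true(all(err <= 2^-16 + 1e-12))
})

test_that("the software exponential quantizes a double-precision core", {
  expect_equal(as.numeric(fx_exp(quantize(0))), 1)
  expect_equal(as.numeric(fx_exp(quantize(1))), hp$e_s1615)
  expect_equal(as.numeric(fx_exp(quantize(12))), 65535.999969482421875)
  # u0.32 output format for arguments <= 0
  expect_equal(as.numeric(fx_exp(quantize(-1), "u0.32")),
               round(exp(-1) * 2^32) / 2^32, tolerance = 1e-12)
})

test_that("format conversion re-rounds payloads both ways", {
  v <- quantize(0.123456789, "u0.32")
  acc <- fx_convert(v, "s16.15")
  expect_equal(acc$raw, round(v$raw / 2^17))
  back <- fx_convert(acc, "u0.32")
  expect_equal(back$raw, acc$raw * 2^17)                 # exact widening
  expect_equal(fx_convert(quantize(5), "u0.32")$raw, 2^32 - 1)  # saturates
  # mixed-format arithmetic promotes to accum
  m <- fx_mul(quantize(0.5, "u0.32"), quantize(2, "s16.15"))
  expect_equal(m$format$name, "s16.15")
  expect_equal(as.numeric(m), 1)
})

test_that("the full fixed-point simulation stays inside format ranges", {
  s <- simulate_neuron(stimulus_protocol(2000, ie_soma = 3),
                       arithmetic = "fixed", gating = "lut")
  expect_equal(s$sat_count, 0)
  s2 <- simulate_neuron(stimulus_protocol(1000, ie_dend = 3), model = "two",
                        arithmetic = "fixed", gating = "lut")
  expect_equal(s2$sat_count, 0)
})
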