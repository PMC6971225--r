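test_that("quantization is exact on the grid, saturating, and idempotent", {
  fmt <- fixed_format()
  expect_identical(fmt$resolution, 2^-18)
  expect_identical(fmt$max_value, 8192 - 2^-18)

  # powers of two are exactly representable
  expect_identical(quantize(0.0078125)$raw, 2048)
  expect_identical(quantize(0)$raw, 0)
  expect_identical(quantize(1)$raw, 262144)

  # out-of-range saturates at the register bounds
  expect_identical(quantize(10000)$raw, 2^31 - 1)
  expect_identical(dequantize(quantize(10000)), 8192 - 2^-18)
  expect_identical(quantize(-10000)$raw, -2^31)

  # quantize(dequantize(.)) is the identity on representable values
  set.seed(3)
  x <- runif(200, -8000, 8000)
  fv <- quantize(x)
  expect_identical(quantize(dequantize(fv))$raw, fv$raw)
  expect_true(all(abs(dequantize(fv) - x) <= 2^-19 + 1e-12))

  expect_error(quantize(NaN), "finite")
  expect_error(fixed_format(32, 12, 18), "total_bits")
})

test_that("shift_mul equals full multiplication for power-of-two coefficients", {
  one <- quantize(1)
  expect_identical(shift_mul(one, 0.25)$raw, 65536)  # M2 of the shift circuit
  expect_identical(shift_mul(one, 16)$raw, 4194304)  # C42 of the shift circuit
  expect_identical(shift_mul(one, 1)$raw, one$raw)
  expect_error(shift_mul(one, 3), "power of two")

  set.seed(11)
  x <- quantize(runif(100, -100, 100))
  for (coeff in c(0.25, 0.5, 16, -2, 2^-7)) {
    ref <- quantize(dequantize(x) * coeff)
    got <- shift_mul(x, coeff)
    # right shifts truncate toward -Inf; allow the 1-ulp floor-vs-round gap
    expect_true(all(abs(got$raw - ref$raw) <= 1), label = paste("coeff", coeff))
    if (coeff >= 1) expect_identical(got$raw, ref$raw)
  }
})

test_that("fixed_step matches its worked examples and preserves the zero state", {
  # improved L-QIF, SA: v' = h * (C41 * 1) with all powers of two, exact
  p <- improved_lqif_params()
  s <- fixed_step("lqif", list(v = 0), I_now = 1, params = p, use_shift = TRUE)
  expect_identical(s$v, 0.00390625)
  expect_false(s$spiked)

  # zero state, zero input is invariant for the one-variable models (the
  # Izhikevich family carries the constant +140 drive and moves)
  for (model in c("qif", "lqif")) {
    s <- fixed_step(model, list(v = 0), I_now = 0, params = neuron_params(model))
    expect_identical(s$v, 0, label = model)
    expect_false(s$spiked)
  }
})

test_that("shift-based and multiply-based improved L-QIF agree bit for bit", {
  p <- improved_lqif_params()
  # single steps over seeded random states
  st <- random_states("lqif", 10000, seed = 21)
  for (fa in c(FALSE, TRUE)) {
    for (j in seq(1, 10000, by = 97)) { # thinned here; exhaustive in acceptance
      a <- fixed_step("lqif", list(v = st$v[j]), st$I[j], st$I1[j],
                      params = p, afferent_type = if (fa) "FA" else "SA",
                      use_shift = TRUE)
      b <- fixed_step("lqif", list(v = st$v[j]), st$I[j], st$I1[j],
                      params = p, afferent_type = if (fa) "FA" else "SA",
                      use_shift = FALSE)
      expect_identical(a$v, b$v)
      expect_identical(a$spiked, b$spiked)
    }
  }
  # and over a full trapezoid trace
  I <- short_trapezoid_current(6)
  cfg <- sim_config(100, afferent_type = "SA", model = "lqif")
  tr_shift <- simulate_trace(cfg, p, I, arithmetic = "shift")
  tr_mul <- simulate_trace(cfg, p, I, arithmetic = "fixed")
  expect_identical(tr_shift$trace$v, tr_mul$trace$v)
  expect_identical(tr_shift$spike_steps, tr_mul$spike_steps)
})

test_that("a 48-fractional-bit register reproduces floating point to 1e-9 per step", {
  wide <- fixed_format(62, 13, 48)
  h <- 0.0078125
  n <- 2500 # per model x afferent type; 10^4 states in acceptance
  for (model in ALL_MODELS) {
    st <- random_states(model, n, seed = match(model, ALL_MODELS))
    step <- tactspike:::step_fun(model)
    for (fa in c(FALSE, TRUE)) {
      at <- if (fa) "FA" else "SA"
      for (j in seq_len(n)) {
        state <- if (model %in% c("izh", "lizh")) {
          list(v = st$v[j], u = st$u[j])
        } else list(v = st$v[j])
        ref <- step(state, st$I[j], st$I1[j], h = h, afferent_type = at)
        got <- fixed_step(model, state, st$I[j], st$I1[j], fmt = wide,
                          afferent_type = at, h = h)
        expect_lt(abs(got$v - ref$v), 1e-9)
        if (!is.null(ref$u)) expect_lt(abs(got$u - ref$u), 1e-9)
      }
    }
  }
})

test_that("Q13.18 spike counts track floating point on the reference runs", {
  amp <- 14
  for (model in ALL_MODELS) {
    for (at in c("SA", "FA")) {
      cfg <- sim_config(100, afferent_type = at, model = model)
      I <- short_trapezoid_current(amp)
      nf <- length(simulate_trace(cfg, current = I, arithmetic = "float",
                                  return_trace = FALSE)$spike_times)
      nq <- length(simulate_trace(cfg, current = I, arithmetic = "fixed",
                                  return_trace = FALSE)$spike_times)
      expect_lte(abs(nq - nf), max(1, ceiling(0.05 * nf)),
                 label = paste(model, at))
    }
  }
})

test_that("saturation is counted, never silently wrapped", {
  # absurd drive overflows the 13 integer bits
  cfg <- sim_config(1, model = "izh")
  tr <- simulate_trace(cfg, neuron_params("izh"),
                       rep(1e6, cfg$n_steps), arithmetic = "fixed")
  expect_gt(tr$overflow_events, 0)
  fmt <- fixed_format()
  expect_true(all(tr$trace$v <= fmt$max_value & tr$trace$v >= fmt$min_value))
})

test_that("register images export as two's-complement hex words", {
  expect_identical(as_hex(quantize(1)), "00040000")
  expect_identical(as_hex(quantize(-1)), "FFFC0000")
  expect_identical(as_hex(quantize(0.0078125)), "00000800")
  path <- tempfile(fileext = ".hex")
  on.exit(unlink(path))
  as_hex(quantize(c(1, -1)), path)
  expect_identical(readLines(path), c("00040000", "FFFC0000"))
})
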