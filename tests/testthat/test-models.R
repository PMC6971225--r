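test_that("single Euler steps reproduce direct substitution into the update rules", {
  h <- 0.0078125

  # Izhikevich, SA, zero input from rest
  s <- step_izh(list(v = -65, u = -13), I_now = 0)
  expect_identical(s$v, -65 + h * (0.04 * 65^2 - 5 * 65 + 140 + 13))
  expect_identical(s$v, -65.0234375)
  expect_identical(s$u, -13) # b*v - u = 0 at this point
  expect_false(s$spiked)

  # linearized Izhikevich at the kink of the absolute-value term
  s <- step_lizh(list(v = -62.5, u = 0), I_now = 0)
  expect_identical(s$v, -62.5 + h * (0 - 20 - 0))
  expect_identical(s$v, -62.65625)

  # QIF with unit quadratic gain
  s <- step_qif(list(v = 1), I_now = 0)
  expect_identical(s$v, 1 + h * 1)

  # L-QIF driven by unit input through C41 = 1
  s <- step_lqif(list(v = 0), I_now = 1)
  expect_identical(s$v, h)

  # zero is a fixed point of the one-variable models
  expect_identical(step_qif(list(v = 0), 0)$v, 0)
  expect_identical(step_lqif(list(v = 0), 0)$v, 0)
})

test_that("the reset rule fires at threshold and uses the pre-step recovery value", {
  # choose v so the computed update crosses 30 mV
  s <- step_izh(list(v = 30, u = 5), I_now = 0)
  expect_true(s$spiked)
  expect_identical(s$v, -65)        # c
  expect_identical(s$u, 5 + 8)      # u[n] + d, not the computed u[n+1] + d
  s <- step_lizh(list(v = 30, u = 5), I_now = 0)
  expect_true(s$spiked)
  expect_identical(s$v, -65)
  expect_identical(s$u, 13)

  # one-variable models reset to v_reset = 0
  s <- step_qif(list(v = 29.9), I_now = 0) # 29.9 + h*29.9^2 > 30
  expect_true(s$spiked)
  expect_identical(s$v, 0)
  p <- neuron_params("lqif", C_in_sa = 1)
  s <- step_lqif(list(v = 29.99), I_now = 500, params = p)
  expect_true(s$spiked)
  expect_identical(s$v, 0)
})

test_that("FA-I afferents respond to input differences only", {
  for (model in ALL_MODELS) {
    step <- tactspike:::step_fun(model)
    st <- if (model %in% c("izh", "lizh")) list(v = -60, u = -10) else list(v = 3)
    # constant input: the difference term vanishes
    with_input <- step(st, I_now = 7, I_next = 7, afferent_type = "FA")
    without <- step(st, I_now = 0, I_next = 0, afferent_type = "FA")
    expect_identical(with_input$v, without$v, label = model)
    # a small jump contributes C_fa * (I_next - I_now) once, outside the
    # bracket (small enough that no reset intervenes)
    p <- neuron_params(model)
    dI <- 1e-4
    jump <- step(st, I_now = 0, I_next = dI, afferent_type = "FA")
    expect_equal(jump$v - without$v, p$C_in_fa * dI, tolerance = 1e-9,
                 label = model)
  }
})

test_that("simulate_trace agrees bit-for-bit with looping the R-level steps", {
  h <- 0.0078125
  n <- 2000
  I <- trapezoid(trapezoid_spec(1, 2, 8, 2, 10), h = h, duration = n * h)$force
  for (model in ALL_MODELS) {
    for (at in c("SA", "FA")) {
      p <- neuron_params(model)
      cfg <- sim_config(n * h, afferent_type = at, model = model)
      tr <- simulate_trace(cfg, p, I)
      step <- tactspike:::step_fun(model)
      st <- tactspike:::initial_state(p)
      v_ref <- numeric(n)
      spikes_ref <- integer(0)
      for (i in seq_len(n)) {
        I1 <- if (i < n) I[i + 1] else I[n]
        st2 <- step(st, I[i], I1, params = p, h = h, afferent_type = at)
        v_ref[i] <- if (st2$spiked) p$v_peak else st2$v
        if (st2$spiked) spikes_ref <- c(spikes_ref, i)
        st <- st2[setdiff(names(st2), "spiked")]
      }
      expect_identical(tr$trace$v, v_ref, label = paste(model, at))
      expect_identical(tr$spike_steps, spikes_ref, label = paste(model, at))
    }
  }
})

test_that("traces are deterministic and never exceed the peak after reset", {
  I <- short_trapezoid_current(14)
  for (model in ALL_MODELS) {
    cfg <- sim_config(100, afferent_type = "SA", model = model)
    a <- simulate_trace(cfg, current = I)
    b <- simulate_trace(cfg, current = I)
    expect_identical(a$trace$v, b$trace$v)
    expect_true(all(a$trace$v <= neuron_params(model)$v_peak))
  }
})

test_that("SA-I fires on the plateau and its rate is monotone in amplitude", {
  amps <- c(2, 5, 10, 15, 20)
  for (model in ALL_MODELS) {
    cfg <- sim_config(100, afferent_type = "SA", model = model)
    counts <- vapply(amps, function(a) {
      tr <- simulate_trace(cfg, current = short_trapezoid_current(a),
                           return_trace = FALSE)
      length(tr$spike_times)
    }, 1L)
    expect_true(all(diff(counts) >= 0), label = model)
    # plateau firing at sufficient amplitude (plateau spans 15-85 ms)
    tr <- simulate_trace(cfg, current = short_trapezoid_current(14),
                         return_trace = FALSE)
    expect_gt(phase_count(tr$spike_times, 15, 85), 0, label = model)
  }
})

test_that("FA-I plateau firing is limited to the residual dynamics of each model", {
  # Izh/L-Izh relax below threshold on the plateau: exactly zero spikes there.
  # QIF/L-QIF are self-excitatory above reset, so a positive residual voltage
  # at ramp end can yield at most one delayed blow-up spike before the state
  # parks at the reset fixed point.
  h <- 0.0078125
  settle <- 10 * h
  for (model in ALL_MODELS) {
    for (arith in c("float", "fixed")) {
      cfg <- sim_config(100, afferent_type = "FA", model = model)
      tr <- simulate_trace(cfg, current = short_trapezoid_current(14),
                           arithmetic = arith, return_trace = FALSE)
      plateau <- phase_count(tr$spike_times, 15, 85, settle_ms = settle)
      if (model %in% c("izh", "lizh")) {
        expect_identical(plateau, 0L, label = paste(model, arith))
      } else {
        expect_lte(plateau, 1L)
      }
      expect_gt(length(tr$spike_times), 0, label = paste(model, arith))
    }
  }
})

test_that("FA-I offset firing is no stronger than onset firing for slower release", {
  # onset ramp 5 ms, offset ramp 25 ms (slower)
  h <- 0.0078125
  n <- as.integer(100 / h)
  t <- seq_len(n) * h
  f <- approx(c(0, 5, 10, 70, 95, 100), c(0, 0, 14, 14, 0, 0), xout = t,
              rule = 2)$y
  for (model in ALL_MODELS) {
    cfg <- sim_config(100, afferent_type = "FA", model = model)
    tr <- simulate_trace(cfg, current = f, return_trace = FALSE)
    onset <- phase_count(tr$spike_times, 5, 10)
    offset <- phase_count(tr$spike_times, 70, 95)
    expect_lte(offset, onset, label = model)
  }
})

test_that("invalid inputs are rejected with diagnostics", {
  expect_error(step_izh(list(v = NaN, u = 0), 0), "finite")
  expect_error(step_izh(list(v = -65), 0), "recovery")
  expect_error(step_qif(list(v = 0), Inf), "finite")
  expect_error(step_qif(list(v = 0), 0, h = 0), "positive")
  cfg <- sim_config(1, model = "qif")
  expect_error(simulate_trace(cfg, current = rep(0, 5)), "length")
  expect_error(sim_config(100, h = -1), "positive")
  expect_error(sim_config(100.003), "multiple")
})
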