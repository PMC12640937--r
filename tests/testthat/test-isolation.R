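# Current isolation and fractional inhibition.

test_that("input resistance follows Ohm's law on constructed deflections", {
  # -10 mV monitoring step; deflection -100 pA -> 100 MOhm, -50 pA -> 200 MOhm
  for (case in list(c(-100, 100), c(-50, 200))) {
    rec <- make_step_recording(deflection = case[1])
    expect_equal(compute_input_resistance(rec$sweeps[[1]], rec$protocol),
                 case[2])
  }
  # I_NaL monitoring step is -95 -> -120 mV (dV = -25 mV)
  rec <- make_step_recording("I_NaL", deflection = -125)
  expect_equal(compute_input_resistance(rec$sweeps[[1]], rec$protocol), 200)
  # zero deflection is unmeasurable
  rec0 <- make_step_recording(deflection = 0)
  expect_error(compute_input_resistance(rec0$sweeps[[1]], rec0$protocol),
               "deflection")
})

test_that("input resistance is recovered from noisy leak-only sweeps", {
  spec <- voltage_clamp_sim_spec(
    control_amplitude = 1e-9,  # effectively leak-only
    input_resistance = 150, noise_sd = 2,
    rundown = list(fast_fraction = 0, fast_tau = 1, slow_rate = 0),
    seed = 11
  )
  rec <- simulate_voltage_clamp_cell(spec, 0)
  r <- vapply(rec$sweeps[1:10], compute_input_resistance, numeric(1),
              protocol = rec$protocol)
  expect_true(all(abs(r - 150) / 150 < 0.05))
})

test_that("passive current reproduces the ohmic leak and cancels a pure-leak sweep", {
  p <- build_standard_protocol("I_NaL")
  dt <- default_sample_interval("I_NaL")
  n <- round(protocol_duration(p) / dt)
  sw <- sweep(dt, numeric(n), 1, "control", 0)
  # V_cmd == V_hold at the start: passive current is the holding current
  ip <- compute_passive_current(sw, p, r_in = 100, holding_current = -15)
  expect_equal(ip[1], -15)
  # -15 mV step with V_hold -95: 80 mV / 100 MOhm = 800 pA above holding
  b <- segment_bounds(p)
  t <- (seq_len(n) - 1) * dt
  at_step <- which(t >= b$t_start[3] & t < b$t_end[3])[1]
  expect_equal(ip[at_step], -15 + 1000 * (-15 - (-95)) / 100)
  expect_error(compute_passive_current(sw, p, r_in = 0), "positive")

  # a simulated leak-only cell is cancelled to within noise
  spec <- voltage_clamp_sim_spec(
    current_type = "I_CaL", control_amplitude = 1e-9,
    input_resistance = 120, holding_current = -30, noise_sd = 2,
    rundown = list(fast_fraction = 0, fast_tau = 1, slow_rate = 0), seed = 3
  )
  rec <- simulate_voltage_clamp_cell(spec, 0)
  swx <- rec$sweeps[[1]]
  r_in <- compute_input_resistance(swx, rec$protocol)
  resid <- swx$current -
    compute_passive_current(swx, rec$protocol, r_in, rec$holding_current)
  # bound on the max of ~8000 noise samples (sigma*sqrt(2*log(n)) ~ 4.2 sigma)
  # plus the leak scaled by the R_in estimation error
  expect_lt(max(abs(resid)), 5 * 2)
})

test_that("reference subtraction averages references pointwise", {
  rec <- make_random_recording(seed = 5)
  sw <- rec$sweeps[[1]]
  # reference == input -> all-zero trace
  out <- subtract_reference(list(sw), list(sw))
  expect_equal(out[[1]]$current, numeric(length(sw$current)))
  # two references -> subtrahend is their pointwise mean
  a <- rec$sweeps[[2]]; b <- rec$sweeps[[3]]
  out2 <- subtract_reference(list(sw), list(a, b))
  expect_equal(out2[[1]]$current, sw$current - (a$current + b$current) / 2)
  expect_equal(out2[[1]]$epoch_label, sw$epoch_label)  # metadata preserved
  short <- sweep(sw$sample_interval, sw$current[-1], 9, "control", 0)
  expect_error(subtract_reference(list(sw), list(short)), "length mismatch")
})

test_that("amplitude measurement applies the window statistic and polarity", {
  p <- build_standard_protocol("hERG")
  dt <- default_sample_interval("hERG")
  n <- round(protocol_duration(p) / dt)
  const <- function(x) sweep(dt, rep(x, n), 1, "control", 0)
  w_mean <- measurement_window(5, statistic = "mean", direction = "outward")
  expect_equal(measure_amplitude(const(100), w_mean, p), 100)
  w_in <- measurement_window(5, statistic = "peak_magnitude", direction = "inward")
  expect_equal(measure_amplitude(const(-50), w_in, p, smooth_ms = 0), -50)
  expect_error(measurement_window(5, t_offset_start = 50, t_offset_end = 10))
  expect_error(
    measure_amplitude(const(1), measurement_window(5, 0, 500), p),
    "outside"
  )
})

test_that("stability surrogate flags drifting amplitude series", {
  t_s <- seq(0, 95, by = 5)
  st <- assess_stability(rep(400, 20), t_s, window_n = 10)
  expect_true(st$stable)
  expect_equal(st$slope, 0)
  decaying <- 400 * (1 - 0.10 / 60 * t_s)  # 10%/min
  st2 <- assess_stability(decaying, t_s, window_n = 10, slope_tolerance = 1)
  expect_false(st2$stable)
  # linear decay of 40 pA/min relative to the window-mean amplitude
  expect_equal(st2$slope, 100 * (-400 * 0.10) / mean(decaying[11:20]),
               tolerance = 1e-6)
  expect_error(assess_stability(1:3, 1:3, window_n = 10), "at least")
})

test_that("fractional inhibition is the last-10-trace amplitude ratio subtracted from unity", {
  # build a recording with programmed amplitudes: control 200 pA, drug 50 pA
  spec <- voltage_clamp_sim_spec(
    control_amplitude = 200, noise_sd = 0,
    rundown = list(fast_fraction = 0, fast_tau = 1, slow_rate = 0),
    washin_tau = 1e-6, seed = 1
  )
  rec <- simulate_voltage_clamp_cell(spec, 3)  # hill(3,1,1) = 0.75 -> amp 50
  fi <- fractional_inhibition(rec, smooth_ms = 0)
  expect_s3_class(fi, "fractional_inhibition")
  expect_equal(fi$fraction_inhibited, 0.75, tolerance = 1e-9)
  expect_equal(fi$n_control, 10L)
  expect_equal(fi$control_amplitude_pA, 200, tolerance = 1e-9)

  # complete block -> 1; no drug effect -> 0
  spec_hi <- voltage_clamp_sim_spec(
    control_amplitude = 200, noise_sd = 0, true_ic50 = 1e-9,
    rundown = list(fast_fraction = 0, fast_tau = 1, slow_rate = 0),
    washin_tau = 1e-6, seed = 1
  )
  expect_equal(
    fractional_inhibition(simulate_voltage_clamp_cell(spec_hi, 10),
                          smooth_ms = 0)$fraction_inhibited,
    1, tolerance = 1e-9
  )
})

test_that("isolation is linear and inhibition ignores common passive components", {
  rec <- make_random_recording(seed = 9)
  sw <- rec$sweeps[[1]]; ref <- rec$sweeps[[3]]
  k <- 3.7
  scale_sweep <- function(s, k) { s$current <- k * s$current; s }
  # subtract_reference commutes with scalar scaling
  lhs <- subtract_reference(list(scale_sweep(sw, k)), list(scale_sweep(ref, k)))
  rhs <- subtract_reference(list(sw), list(ref))
  expect_equal(lhs[[1]]$current, k * rhs[[1]]$current)
  # passive current scales with 1/R_in (ohmic linearity)
  p <- rec$protocol
  ip1 <- compute_passive_current(sw, p, r_in = 100, holding_current = 0)
  ip2 <- compute_passive_current(sw, p, r_in = 100 / k, holding_current = 0)
  expect_equal(ip2, k * ip1)

  # adding a common leak to both epochs does not move inhibition after
  # passive subtraction: compare two simulated cells differing only in R_in
  base <- list(fast_fraction = 0, fast_tau = 1, slow_rate = 0)
  f <- vapply(c(100, 400), function(rin) {
    spec <- voltage_clamp_sim_spec(
      current_type = "I_CaL", control_amplitude = 500, noise_sd = 0,
      input_resistance = rin, rundown = base, washin_tau = 1e-6, seed = 2
    )
    fractional_inhibition(simulate_voltage_clamp_cell(spec, 1),
                          smooth_ms = 0)$fraction_inhibited
  }, numeric(1))
  expect_equal(f[1], f[2], tolerance = 1e-9)
  expect_equal(f[1], 0.5, tolerance = 1e-9)
})
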