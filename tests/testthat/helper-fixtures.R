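# In-code fixtures shared across test files.

# A minimal recording whose monitoring-step deflection is set directly:
# baseline current 0, `deflection` pA during the monitoring step, and an
# arbitrary constant elsewhere. Used for Ohm's-law unit checks.
make_step_recording <- function(current_type = "hERG", deflection = -100,
                                n_sweeps = 1L) {
  protocol <- build_standard_protocol(current_type)
  dt <- default_sample_interval(current_type)
  b <- segment_bounds(protocol)
  step_i <- monitoring_step_index(protocol)
  t <- seq(0, protocol_duration(protocol) - dt / 2, by = dt)
  cur <- numeric(length(t))
  cur[t >= b$t_start[step_i] & t < b$t_end[step_i]] <- deflection
  sweeps <- lapply(seq_len(n_sweeps), function(k) {
    sweep(dt, cur, sweep_index = k, epoch_label = "control",
          wall_time = (k - 1) * protocol$inter_sweep_interval)
  })
  cell_recording("step_cell", current_type, protocol, sweeps,
                 holding_current = 0, input_resistance = NA_real_)
}

# Idealized AP train: instant (single-sample) rise to peak at each stimulus,
# linear repolarization from peak to rest over `repol_ms`, then rest.
# Closed-form APDx = (x/100) * repol_ms (onset and peak coincide).
make_linear_ap_train <- function(n_beats = 3L, rest = -85, peak = 15,
                                 repol_ms = 300, interval = 1000,
                                 sample_interval = 0.05) {
  stim <- 100 + interval * (seq_len(n_beats) - 1L)
  total <- stim[n_beats] + interval
  t <- seq(0, total - sample_interval / 2, by = sample_interval)
  v <- rep(rest, length(t))
  for (s in stim) {
    sel <- t >= s & t < s + repol_ms
    v[sel] <- peak - (peak - rest) * (t[sel] - s) / repol_ms
  }
  ap_train(sample_interval, v, stim, pacing_rate = 1000 / interval,
           tissue_id = "linear", epoch_label = "vehicle")
}

# Random small recording for I/O round-trip tests.
make_random_recording <- function(seed = 1, current_type = "hERG",
                                  n_sweeps = 3L) {
  set.seed(seed)
  protocol <- build_standard_protocol(current_type)
  dt <- default_sample_interval(current_type)
  n <- round(protocol_duration(protocol) / dt)
  labels <- c("control", "drug:0.5", "reference_blocker")
  sweeps <- lapply(seq_len(n_sweeps), function(k) {
    sweep(dt, rnorm(n, 0, 50), sweep_index = k,
          epoch_label = labels[min(k, length(labels))],
          wall_time = (k - 1) * 5)
  })
  cell_recording("rand_cell", current_type, protocol, sweeps,
                 holding_current = -12.5, input_resistance = 150.25,
                 temperature = 36.5)
}
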