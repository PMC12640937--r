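#' Voltage-clamp simulation specification
#'
#' Ground-truth parameters for the synthetic voltage-clamp generator. A
#' simulated cell produces a drug-sensitive current template scaled by a
#' two-phase rundown (fast exponential phase plus a constant slow
#' percentage rate) and by a Hill-governed block that washes in
#' exponentially, sitting on an ohmic leak consistent with the programmed
#' input resistance, plus additive Gaussian recording noise.
#'
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @param true_ic50 ground-truth IC50 (uM).
#' @param true_n_h ground-truth Hill coefficient.
#' @param control_amplitude drug-sensitive amplitude at time zero (pA,
#'   magnitude).
#' @param rundown list with `fast_fraction` (fraction of amplitude lost in
#'   the fast phase), `fast_tau` (min) and `slow_rate` (%/min).
#' @param washin_tau wash-in time constant (min).
#' @param input_resistance resting input resistance (MOhm).
#' @param holding_current resting holding current (pA).
#' @param noise_sd additive Gaussian noise SD (pA).
#' @param fraction_sd per-cell SD of fractional inhibition used by the
#'   trace-free generator [simulate_concentration_response()].
#' @param concentrations drug concentrations of the design (uM).
#' @param n_cells_per_concentration cells per concentration.
#' @param n_control_sweeps,n_drug_sweeps,n_reference_sweeps sweeps per
#'   epoch.
#' @param seed RNG seed (explicit; no global random state).
#' @return list of class `vc_sim_spec`.
#' @export
voltage_clamp_sim_spec <- function(current_type = "hERG",
                                   true_ic50 = 1,
                                   true_n_h = 1,
                                   control_amplitude = 800,
                                   rundown = list(fast_fraction = 0.1,
                                                  fast_tau = 0.5,
                                                  slow_rate = 0.4),
                                   washin_tau = 0.3,
                                   input_resistance = 150,
                                   holding_current = -20,
                                   noise_sd = 8,
                                   fraction_sd = 0.05,
                                   concentrations = c(0.1, 0.3, 1, 3, 10),
                                   n_cells_per_concentration = 5L,
                                   n_control_sweeps = 40L,
                                   n_drug_sweeps = 36L,
                                   n_reference_sweeps = 5L,
                                   seed = 1L) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  stopifnot(
    true_ic50 > 0, true_n_h > 0, control_amplitude > 0,
    rundown$fast_fraction >= 0, rundown$fast_tau > 0, rundown$slow_rate >= 0,
    washin_tau > 0, input_resistance > 0, noise_sd >= 0, fraction_sd >= 0,
    all(concentrations > 0), n_cells_per_concentration >= 1L
  )
  structure(
    list(
      current_type = current_type, true_ic50 = true_ic50, true_n_h = true_n_h,
      control_amplitude = control_amplitude, rundown = rundown,
      washin_tau = washin_tau, input_resistance = input_resistance,
      holding_current = holding_current, noise_sd = noise_sd,
      fraction_sd = fraction_sd, concentrations = concentrations,
      n_cells_per_concentration = as.integer(n_cells_per_concentration),
      n_control_sweeps = as.integer(n_control_sweeps),
      n_drug_sweeps = as.integer(n_drug_sweeps),
      n_reference_sweeps = as.integer(n_reference_sweeps),
      seed = as.integer(seed)
    ),
    class = "vc_sim_spec"
  )
}

# Unit-amplitude drug-sensitive current template along the protocol. The
# template is zero during the baseline hold and the monitoring step (the
# channels are closed there), and its window statistic under the default
# measurement window equals +/-1, so the programmed amplitude is exactly
# what the analysis should recover.
current_template <- function(current_type, protocol, sample_interval) {
  b <- segment_bounds(protocol)
  t <- seq(0, protocol_duration(protocol) - sample_interval / 2,
           by = sample_interval)
  shape <- numeric(length(t))
  seg_rel <- function(i) {
    sel <- t >= b$t_start[i] & t < b$t_end[i]
    list(sel = sel, tr = t[sel] - b$t_start[i],
         dur = b$t_end[i] - b$t_start[i])
  }
  if (current_type == "hERG") {
    s4 <- seg_rel(4L)  # +40 mV step: activation, partly inactivated
    shape[s4$sel] <- 0.5 * (1 - exp(-s4$tr / 100))
    s5 <- seg_rel(5L)  # ramp: recovery tail peaking at 30% of the ramp
    start <- 0.5 * (1 - exp(-s4$dur / 100))
    peak_t <- 0.3 * s5$dur
    up <- s5$tr <= peak_t
    shape[s5$sel][up] <- start + (1 - start) * s5$tr[up] / peak_t
    shape[s5$sel][!up] <- (s5$dur - s5$tr[!up]) / (s5$dur - peak_t)
  } else if (current_type == "I_CaL") {
    s4 <- seg_rel(4L)  # 0 mV step: inward transient (alpha shape, peak -1)
    tau <- 5
    shape[s4$sel] <- -(s4$tr / tau) * exp(1 - s4$tr / tau)
    s5 <- seg_rel(5L)  # +30 mV step: smaller sustained inward component
    shape[s5$sel] <- -0.35 * exp(-s5$tr / 80)
  } else {
    s3 <- seg_rel(3L)  # -15 mV step: sustained late current
    shape[s3$sel] <- -0.9
    s4 <- seg_rel(4L)  # +40 mV step: reduced driving force
    shape[s4$sel] <- -0.5
    s5 <- seg_rel(5L)  # ramp: driving force grows as V falls; mean of the
    shape[s5$sel] <- -(0.6 + 0.8 * s5$tr / s5$dur)  # middle 50% is exactly -1
  }
  shape
}

# Multi-phase rundown factor at time t (minutes from whole-cell formation).
rundown_factor <- function(t_min, rundown) {
  fast <- 1 - rundown$fast_fraction * (1 - exp(-t_min / rundown$fast_tau))
  slow <- exp(-rundown$slow_rate / 100 * t_min)
  fast * slow
}

#' Simulate one voltage-clamp cell
#'
#' Generates a full [cell_recording()] for one cell of the design: control
#' sweeps, drug sweeps at the given concentration (block washes in
#' exponentially towards the Hill steady state), and trailing
#' reference-blocker sweeps in which the drug-sensitive current is fully
#' eliminated. Deterministic under a fixed seed.
#'
#' @param spec a [voltage_clamp_sim_spec()].
#' @param concentration drug concentration (uM); 0 simulates a
#'   vehicle-only exposure (no block).
#' @param cell_id cell identifier.
#' @param seed RNG seed; defaults to the spec seed.
#' @return a [cell_recording()].
#' @export
simulate_voltage_clamp_cell <- function(spec, concentration,
                                        cell_id = "sim_cell",
                                        seed = spec$seed) {
  protocol <- build_standard_protocol(spec$current_type)
  dt <- default_sample_interval(spec$current_type)
  template <- current_template(spec$current_type, protocol, dt)
  n_samp <- length(template)
  v_cmd <- command_voltage(protocol, (seq_len(n_samp) - 1L) * dt)
  v_hold <- protocol$segments[[1L]]$v_start
  leak <- spec$holding_current + 1000 * (v_cmd - v_hold) / spec$input_resistance
  isi <- protocol$inter_sweep_interval
  b_ss <- if (concentration > 0) {
    hill_inhibition(concentration, spec$true_ic50, spec$true_n_h)
  } else 0
  n_total <- spec$n_control_sweeps + spec$n_drug_sweeps + spec$n_reference_sweeps
  drug_start_s <- spec$n_control_sweeps * isi
  with_local_seed(seed, {
    sweeps <- lapply(seq_len(n_total), function(k) {
      wall_s <- (k - 1L) * isi
      if (k <= spec$n_control_sweeps) {
        label <- "control"; block <- 0; gone <- FALSE
      } else if (k <= spec$n_control_sweeps + spec$n_drug_sweeps) {
        label <- if (concentration > 0) {
          sprintf("drug:%.10g", concentration)
        } else "control"
        block <- b_ss * (1 - exp(-((wall_s - drug_start_s) / 60) / spec$washin_tau))
        gone <- FALSE
      } else {
        label <- "reference_blocker"; block <- 0; gone <- TRUE
      }
      amp <- if (gone) 0 else {
        spec$control_amplitude * rundown_factor(wall_s / 60, spec$rundown) *
          (1 - block)
      }
      noise <- if (spec$noise_sd > 0) stats::rnorm(n_samp, 0, spec$noise_sd) else 0
      sweep(dt, amp * template + leak + noise, sweep_index = k,
            epoch_label = label, wall_time = wall_s)
    })
    cell_recording(
      cell_id = cell_id, current_type = spec$current_type,
      protocol = protocol, sweeps = sweeps,
      holding_current = spec$holding_current,
      input_resistance = spec$input_resistance
    )
  })
}

#' Simulate a concentration-response table without traces
#'
#' Shortcut generator for fit-level studies: per-cell fractional inhibition
#' is drawn as the Hill value plus Gaussian noise (`fraction_sd`),
#' truncated at 1 from above (complete block cannot be exceeded); negative
#' values are retained. Deterministic under seed.
#'
#' @param spec a [voltage_clamp_sim_spec()].
#' @param seed RNG seed; defaults to the spec seed.
#' @return data.frame of concentration-inhibition points with columns
#'   `cell_id`, `current_type`, `concentration_uM`, `fraction_inhibited`.
#' @export
simulate_concentration_response <- function(spec, seed = spec$seed) {
  design <- expand.grid(
    cell = seq_len(spec$n_cells_per_concentration),
    concentration_uM = spec$concentrations
  )
  truth <- hill_inhibition(design$concentration_uM, spec$true_ic50, spec$true_n_h)
  frac <- with_local_seed(seed, {
    pmin(1, truth + stats::rnorm(nrow(design), 0, spec$fraction_sd))
  })
  data.frame(
    cell_id = sprintf("c%g_%d", design$concentration_uM, design$cell),
    current_type = spec$current_type,
    concentration_uM = design$concentration_uM,
    fraction_inhibited = frac,
    stringsAsFactors = FALSE
  )
}

#' AP-train simulation specification
#'
#' Ground truth for the synthetic paced AP generator. The baseline
#' morphology (resting potential, peak, APD30/50/90 anchors) emulates an
#' adult human ventricular trabecula; per-beat APD90 jitter is i.i.d.
#' Gaussian with proportional co-variation of APD30/50 (the minimal model
#' under which STV has a closed form). Drug modes apply percent effects to
#' the three anchors and the amplitude:
#'
#' * `none`: vehicle.
#' * `herg_block`: late-phase prolongation (+8/+20/+35% on APD30/50/90).
#' * `ical_selective`: near-equal shortening (-8/-8/-8%).
#' * `mixed_block`: early phases shortened most (-30/-20/-10%).
#' * `inal_block`: late-phase shortening (-5/-8/-12%), -5% amplitude.
#'
#' @param rest,peak resting and peak potential (mV).
#' @param apd30,apd50,apd90 baseline anchors (ms), strictly increasing.
#' @param jitter_sd beat-to-beat APD90 jitter SD (ms).
#' @param pacing_rate pacing rate (Hz); the pacing interval must exceed
#'   APD90 plus a 100 ms margin.
#' @param n_beats number of paced beats.
#' @param drug_mode one of the modes above.
#' @param drug_effects optional numeric length-3 override of the percent
#'   effects on APD30/50/90.
#' @param amplitude_effect percent effect on AP amplitude.
#' @param tissue_id tissue identifier.
#' @param seed RNG seed.
#' @return list of class `ap_sim_spec`.
#' @export
ap_sim_spec <- function(rest = -85, peak = 35,
                        apd30 = 200, apd50 = 260, apd90 = 320,
                        jitter_sd = 1.25, pacing_rate = 1, n_beats = 32L,
                        drug_mode = c("none", "herg_block", "ical_selective",
                                      "mixed_block", "inal_block"),
                        drug_effects = NULL, amplitude_effect = NULL,
                        tissue_id = "sim_tissue", seed = 1L) {
  drug_mode <- match.arg(drug_mode)
  stopifnot(apd30 < apd50, apd50 < apd90, jitter_sd >= 0, peak > rest)
  defaults <- list(
    none = list(apd = c(0, 0, 0), amp = 0),
    herg_block = list(apd = c(8, 20, 35), amp = 0),
    ical_selective = list(apd = c(-8, -8, -8), amp = 0),
    mixed_block = list(apd = c(-30, -20, -10), amp = 0),
    inal_block = list(apd = c(-5, -8, -12), amp = -5)
  )[[drug_mode]]
  drug_effects <- drug_effects %||% defaults$apd
  amplitude_effect <- amplitude_effect %||% defaults$amp
  eff90 <- apd90 * (1 + drug_effects[3L] / 100)
  if (1000 / pacing_rate <= eff90 + 100)
    stop("pacing interval must exceed APD90 plus a 100 ms margin")
  structure(
    list(
      rest = rest, peak = peak, apd30 = apd30, apd50 = apd50, apd90 = apd90,
      jitter_sd = jitter_sd, pacing_rate = pacing_rate,
      n_beats = as.integer(n_beats), drug_mode = drug_mode,
      drug_effects = drug_effects, amplitude_effect = amplitude_effect,
      tissue_id = tissue_id, seed = as.integer(seed)
    ),
    class = "ap_sim_spec"
  )
}

# Monotone repolarization waveform for one beat, sampled on `tb` (ms from
# beat onset reference). Returns voltage samples.
ap_beat_waveform <- function(tb, rest, peak, apd30, apd50, apd90,
                             rise_ms = 1.5, latency_ms = 2) {
  amp <- peak - rest
  # the 10% crossing of the half-cosine upstroke defines APD time zero
  u10 <- acos(1 - 0.2) / pi * rise_ms
  t_up <- latency_ms            # upstroke start after the stimulus
  t0 <- t_up + u10              # AP onset as measured by the analyzer
  v <- rep(rest, length(tb))
  up <- tb >= t_up & tb < t_up + rise_ms
  v[up] <- rest + amp * (1 - cos(pi * (tb[up] - t_up) / rise_ms)) / 2
  # monotone repolarization through the programmed percent anchors
  knots_t <- c(t_up + rise_ms, t0 + apd30, t0 + apd50, t0 + apd90,
               t0 + apd90 + 0.4 * (apd90 - apd30))
  knots_v <- c(peak, peak - 0.3 * amp, peak - 0.5 * amp, peak - 0.9 * amp,
               rest)
  f <- stats::splinefun(knots_t, knots_v, method = "monoH.FC")
  rep_sel <- tb >= knots_t[1L] & tb < knots_t[length(knots_t)]
  v[rep_sel] <- f(tb[rep_sel])
  v[tb >= knots_t[length(knots_t)]] <- rest
  v
}

#' Simulate a paced AP train
#'
#' Builds each beat as rest, fast sigmoidal upstroke, monotone
#' repolarization passing exactly through the three programmed
#' percent-repolarization anchors (shape-preserving monotone
#' interpolation), then rest. Per-beat APD90 jitter is i.i.d. Gaussian;
#' APD30/50 co-vary proportionally so the anchor ordering is preserved.
#' Deterministic under seed.
#'
#' @param spec an [ap_sim_spec()].
#' @param sample_interval sample interval in ms (20 kHz default).
#' @param seed RNG seed; defaults to the spec seed.
#' @return an [ap_train()], with attribute `"truth"` carrying the per-beat
#'   programmed anchors.
#' @export
simulate_ap_train <- function(spec, sample_interval = 0.05, seed = spec$seed) {
  interval <- 1000 / spec$pacing_rate
  stim <- 100 + interval * (seq_len(spec$n_beats) - 1L)
  total_ms <- stim[length(stim)] + interval
  t <- seq(0, total_ms - sample_interval / 2, by = sample_interval)
  v <- rep(spec$rest, length(t))
  eff <- 1 + spec$drug_effects / 100
  base30 <- spec$apd30 * eff[1L]
  base50 <- spec$apd50 * eff[2L]
  base90 <- spec$apd90 * eff[3L]
  amp_scale <- 1 + spec$amplitude_effect / 100
  peak <- spec$rest + (spec$peak - spec$rest) * amp_scale
  truth <- with_local_seed(seed, {
    lapply(seq_len(spec$n_beats), function(i) {
      # jitter APD90, co-vary APD30/50 proportionally; resample degenerate draws
      repeat {
        d <- stats::rnorm(1, 0, spec$jitter_sd)
        s <- (base90 + d) / base90
        if (s > 0 && base30 * s < base50 * s && base50 * s < base90 * s) break
      }
      list(apd30 = base30 * s, apd50 = base50 * s, apd90 = base90 * s)
    })
  })
  for (i in seq_len(spec$n_beats)) {
    sel <- t >= stim[i] & t < stim[i] + interval
    v[sel] <- ap_beat_waveform(
      t[sel] - stim[i], spec$rest, peak,
      truth[[i]]$apd30, truth[[i]]$apd50, truth[[i]]$apd90
    )
  }
  label <- if (spec$drug_mode == "none") "vehicle" else {
    paste0("drug:", spec$drug_mode)
  }
  out <- ap_train(
    sample_interval = sample_interval, voltage = v, stimulus_times = stim,
    pacing_rate = spec$pacing_rate, tissue_id = spec$tissue_id,
    epoch_label = label
  )
  attr(out, "truth") <- data.frame(
    apd30 = vapply(truth, `[[`, numeric(1), "apd30"),
    apd50 = vapply(truth, `[[`, numeric(1), "apd50"),
    apd90 = vapply(truth, `[[`, numeric(1), "apd90")
  )
  out
}
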