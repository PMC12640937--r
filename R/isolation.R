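#' Isolation method for the drug-sensitive current
#'
#' Two isolation routes are supported: subtraction of the averaged residual
#' current recorded under a saturating reference blocker (E-4031 for hERG,
#' tetracaine for I_NaL, verapamil for I_CaL cells with endogenous nonlinear
#' currents), or subtraction of the passive ohmic component computed from
#' the resting input resistance.
#'
#' @param kind `"blocker_subtraction"` or `"passive_subtraction"`.
#' @param reference_blocker `"E-4031"`, `"tetracaine"`, `"verapamil"`, or
#'   `"none"` (required for passive subtraction).
#' @return an object of class `isolation_method`.
#' @export
isolation_method <- function(kind = c("blocker_subtraction", "passive_subtraction"),
                             reference_blocker = c("none", "E-4031",
                                                   "tetracaine", "verapamil")) {
  kind <- match.arg(kind)
  reference_blocker <- match.arg(reference_blocker)
  if (kind == "passive_subtraction" && reference_blocker != "none")
    stop("passive_subtraction takes no reference blocker")
  if (kind == "blocker_subtraction" && reference_blocker == "none")
    stop("blocker_subtraction requires a reference blocker")
  structure(list(kind = kind, reference_blocker = reference_blocker),
            class = "isolation_method")
}

#' Default isolation method per current type
#'
#' hERG and I_NaL use reference-blocker subtraction (E-4031, tetracaine);
#' I_CaL uses passive subtraction.
#'
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @return an [isolation_method()].
#' @export
default_isolation_method <- function(current_type) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  switch(current_type,
    hERG = isolation_method("blocker_subtraction", "E-4031"),
    I_NaL = isolation_method("blocker_subtraction", "tetracaine"),
    I_CaL = isolation_method("passive_subtraction", "none")
  )
}

#' Resting input resistance from the monitoring step
#'
#' Applies Ohm's law to the current deflection elicited by the
#' hyperpolarizing monitoring step: `R_in = dV / dI`, where `dI` is the mean
#' current over the last 50% of the step minus the pre-step baseline (mean
#' over the last 50% of the preceding segment).
#'
#' @param sweep a [sweep()].
#' @param protocol the sweep's [voltage_protocol()].
#' @return input resistance in MOhm (positive, finite).
#' @export
#' @examples
#' # a -10 mV step deflecting the current by -100 pA gives 100 MOhm
compute_input_resistance <- function(sweep, protocol) {
  step_i <- monitoring_step_index(protocol)
  if (step_i < 2L) stop("monitoring step has no preceding baseline segment")
  b <- segment_bounds(protocol)
  t <- sweep_times(sweep)
  half_mean <- function(i) {
    mid <- (b$t_start[i] + b$t_end[i]) / 2
    sel <- t >= mid & t < b$t_end[i]
    if (!any(sel)) stop("segment ", i, " has no samples in its second half")
    mean(sweep$current[sel])
  }
  delta_v <- b$v_end[step_i] - b$v_end[step_i - 1L]          # mV
  delta_i <- half_mean(step_i) - half_mean(step_i - 1L)      # pA
  if (abs(delta_i) < 1e-9)
    stop("no measurable current deflection during the monitoring step")
  r_in <- 1000 * delta_v / delta_i                           # mV/pA -> MOhm
  if (!is.finite(r_in) || r_in <= 0)
    stop("non-physical input resistance: ", format(r_in))
  r_in
}

#' Passive (leak) current along the protocol
#'
#' Ohmic leak referenced to the holding condition:
#' `I_passive(t) = I_hold + (V_cmd(t) - V_hold) / R_in`, evaluated
#' sample-wise. `V_hold` is the voltage of the first protocol segment.
#'
#' @param sweep a [sweep()] (defines the sample grid).
#' @param protocol the sweep's [voltage_protocol()].
#' @param r_in input resistance in MOhm (> 0).
#' @param holding_current resting holding current in pA.
#' @return numeric vector of passive current (pA), one value per sample.
#' @export
compute_passive_current <- function(sweep, protocol, r_in, holding_current = 0) {
  if (!is.finite(r_in) || r_in <= 0) stop("r_in must be a positive resistance (MOhm)")
  v_hold <- protocol$segments[[1L]]$v_start
  v <- command_voltage(protocol, sweep_times(sweep))
  holding_current + 1000 * (v - v_hold) / r_in               # mV/MOhm -> pA
}

#' Subtract the averaged reference-blocker current
#'
#' The residual traces recorded under a saturating reference blocker are
#' averaged pointwise and subtracted from every input sweep, isolating the
#' blocker-sensitive (drug-sensitive) component. Metadata are preserved.
#'
#' @param sweeps list of [sweep()]s to isolate.
#' @param reference_sweeps list of one or more reference-blocker [sweep()]s
#'   recorded under the same protocol and sampling.
#' @return list of isolated sweeps.
#' @export
subtract_reference <- function(sweeps, reference_sweeps) {
  if (!length(reference_sweeps)) stop("at least one reference sweep is required")
  n <- length(sweeps[[1L]]$current)
  dt <- sweeps[[1L]]$sample_interval
  for (sw in c(sweeps, reference_sweeps)) {
    if (length(sw$current) != n)
      stop("sweep length mismatch between input and reference sweeps")
    if (!isTRUE(all.equal(sw$sample_interval, dt)))
      stop("sample interval mismatch between input and reference sweeps")
  }
  ref <- rowMeans(do.call(cbind, lapply(reference_sweeps, `[[`, "current")))
  lapply(sweeps, function(sw) {
    sw$current <- sw$current - ref
    sw
  })
}

#' Summary amplitude of an isolated sweep within a window
#'
#' Quantifies the drug-sensitive current in the configured
#' [measurement_window()]: `peak_magnitude` takes the extremum of the
#' stated polarity (maximum for outward currents, minimum for inward);
#' `mean` takes the time average. For peak measurements the trace is first
#' smoothed with a short centered moving average (`smooth_ms`) so that the
#' extremum is not dominated by single-sample noise, mirroring the hardware
#' low-pass filtering applied during acquisition.
#'
#' @param sweep an isolated [sweep()].
#' @param window a [measurement_window()].
#' @param protocol the sweep's [voltage_protocol()].
#' @param smooth_ms moving-average width (ms) applied before peak picking;
#'   `0` disables smoothing. Ignored for the `mean` statistic.
#' @return signed amplitude in pA.
#' @export
measure_amplitude <- function(sweep, window, protocol, smooth_ms = 1) {
  b <- segment_bounds(protocol)
  if (window$segment_index > nrow(b)) stop("window names a missing segment")
  t0 <- b$t_start[window$segment_index]
  seg_dur <- b$t_end[window$segment_index] - t0
  w_end <- window$t_offset_end %||% seg_dur
  if (window$t_offset_start < 0 || w_end > seg_dur + 1e-9)
    stop("window lies outside its protocol segment")
  t <- sweep_times(sweep)
  sel <- t >= t0 + window$t_offset_start & t < t0 + w_end
  if (!any(sel)) stop("measurement window contains no samples")
  x <- sweep$current[sel]
  if (window$statistic == "mean") return(mean(x))
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / sweep$sample_interval))
    x <- moving_average(x, k)
  }
  if (window$direction == "outward") max(x) else min(x)
}

#' Amplitude-stability surrogate
#'
#' Automated stand-in for the electrophysiologist's online stability
#' judgement: a least-squares slope of the relative amplitude (amplitude
#' divided by its window mean) over the last `window_n` sweeps, expressed
#' in %/min. The epoch is called stable when the absolute slope does not
#' exceed `slope_tolerance`.
#'
#' @param amplitudes numeric amplitude series (one per sweep, in recording
#'   order).
#' @param wall_times sweep start times in seconds, same length.
#' @param window_n number of trailing sweeps entering the slope fit.
#' @param slope_tolerance maximal absolute slope (%/min) still called stable.
#' @param reference amplitude against which the slope is normalised;
#'   defaults to the window mean. For a drug epoch the control amplitude is
#'   the natural reference: drift is then measured in the same units as the
#'   fractional-inhibition error it would induce, and a strongly blocked
#'   (small) current is not penalised for noise on a near-zero mean.
#' @return list with `stable` (logical) and `slope` (%/min).
#' @export
assess_stability <- function(amplitudes, wall_times, window_n = 20L,
                             slope_tolerance = 1, reference = NULL) {
  n <- length(amplitudes)
  if (n < window_n)
    stop("need at least ", window_n, " amplitudes to assess stability")
  idx <- (n - window_n + 1L):n
  a <- amplitudes[idx]
  t_min <- wall_times[idx] / 60
  rel <- a / (reference %||% mean(a))
  slope <- 100 * unname(stats::coef(stats::lm(rel ~ t_min))[2L])  # %/min
  list(stable = abs(slope) <= slope_tolerance, slope = slope)
}

# Isolate the sweeps of one epoch according to the isolation method.
isolate_sweeps <- function(recording, sweeps, isolation) {
  if (isolation$kind == "blocker_subtraction") {
    ref <- epoch_sweeps(recording, "reference_blocker")
    if (!length(ref))
      stop("recording has no reference_blocker sweeps for blocker subtraction")
    subtract_reference(sweeps, ref)
  } else {
    lapply(sweeps, function(sw) {
      r_in <- compute_input_resistance(sw, recording$protocol)
      sw$current <- sw$current -
        compute_passive_current(sw, recording$protocol, r_in,
                                recording$holding_current %||% 0)
      sw
    })
  }
}

#' Per-cell fractional inhibition
#'
#' Isolates the drug-sensitive component of every sweep, measures the
#' window amplitude sweep by sweep, gates both epochs on amplitude
#' stability, and computes for each drug concentration
#' `1 - mean(last n_traces drug amplitudes) / mean(last n_traces control
#' amplitudes)`. Values above 1 cannot occur by construction; values below
#' 0 (current growth) are retained.
#'
#' @param recording a [cell_recording()].
#' @param isolation an [isolation_method()]; default per current type.
#' @param window a [measurement_window()]; default per current type.
#' @param n_traces number of trailing traces averaged per epoch (10, as
#'   used for potency estimation).
#' @param require_stability error (rather than warn) when an epoch fails
#'   the stability gate.
#' @param stability_n,slope_tolerance passed to [assess_stability()].
#' @param smooth_ms passed to [measure_amplitude()].
#' @return data.frame of class `fractional_inhibition`, one row per drug
#'   concentration: `cell_id`, `current_type`, `concentration_uM`,
#'   `fraction_inhibited`, `n_control`, `n_drug`, `control_amplitude_pA`,
#'   `control_slope_pct_min`, `drug_slope_pct_min`.
#' @export
fractional_inhibition <- function(recording,
                                  isolation = default_isolation_method(recording$current_type),
                                  window = default_measurement_window(recording$current_type,
                                                                      recording$protocol),
                                  n_traces = 10L,
                                  require_stability = TRUE,
                                  stability_n = 20L,
                                  slope_tolerance = 1,
                                  smooth_ms = 1) {
  ctrl <- epoch_sweeps(recording, "control")
  if (length(ctrl) < n_traces)
    stop("control epoch has fewer than ", n_traces, " sweeps")
  amp_of <- function(sweeps) {
    iso <- isolate_sweeps(recording, sweeps, isolation)
    vapply(iso, measure_amplitude, numeric(1),
           window = window, protocol = recording$protocol,
           smooth_ms = smooth_ms)
  }
  gate <- function(amps, times, label, reference = NULL) {
    st <- assess_stability(amps, times, window_n = min(stability_n, length(amps)),
                           slope_tolerance = slope_tolerance,
                           reference = reference)
    if (!st$stable) {
      msg <- sprintf("%s epoch of cell %s unstable: slope %.2f %%/min",
                     label, recording$cell_id, st$slope)
      if (require_stability) stop(msg) else warning(msg, call. = FALSE)
    }
    st$slope
  }
  ctrl_amp <- amp_of(ctrl)
  ctrl_t <- vapply(ctrl, `[[`, numeric(1), "wall_time")
  ctrl_slope <- gate(ctrl_amp, ctrl_t, "control")
  ctrl_mean <- mean(utils::tail(ctrl_amp, n_traces))
  if (abs(ctrl_mean) < 1e-9)
    stop("control amplitude is indistinguishable from zero")
  kinds <- vapply(recording$sweeps, function(s) parse_epoch_label(s$epoch_label)$kind,
                  character(1))
  concs <- vapply(recording$sweeps, function(s) parse_epoch_label(s$epoch_label)$concentration,
                  numeric(1))
  drug_concs <- unique(concs[kinds == "drug"])
  if (!length(drug_concs)) stop("recording has no drug epoch")
  rows <- lapply(drug_concs, function(conc) {
    dr <- epoch_sweeps(recording, "drug", conc)
    if (length(dr) < n_traces)
      stop("drug epoch at ", conc, " uM has fewer than ", n_traces, " sweeps")
    dr_amp <- amp_of(dr)
    dr_t <- vapply(dr, `[[`, numeric(1), "wall_time")
    dr_slope <- gate(dr_amp, dr_t, sprintf("drug (%g uM)", conc),
                     reference = ctrl_mean)
    data.frame(
      cell_id = recording$cell_id,
      current_type = recording$current_type,
      concentration_uM = conc,
      fraction_inhibited = 1 - mean(utils::tail(dr_amp, n_traces)) / ctrl_mean,
      n_control = as.integer(n_traces),
      n_drug = as.integer(n_traces),
      control_amplitude_pA = ctrl_mean,
      control_slope_pct_min = ctrl_slope,
      drug_slope_pct_min = dr_slope,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fractional_inhibition", class(out))
  out
}
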