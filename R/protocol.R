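#' Voltage-protocol segment
#'
#' A protocol is an ordered, contiguous list of segments. A `hold` or `step`
#' segment clamps the command at a constant voltage (`v_start == v_end`); a
#' `ramp` moves linearly from `v_start` to `v_end` over `duration`.
#'
#' @param kind `"hold"`, `"step"` or `"ramp"`.
#' @param v_start,v_end command voltage (mV) at the start/end of the segment.
#'   For `hold`/`step`, `v_end` defaults to `v_start` and must equal it.
#' @param duration segment duration in ms, strictly positive.
#' @return an object of class `protocol_segment`.
#' @export
protocol_segment <- function(kind, v_start, v_end = v_start, duration) {
  kind <- match.arg(kind, c("hold", "step", "ramp"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("segment duration must be a single positive number (ms)")
  if (kind != "ramp" && !isTRUE(all.equal(v_start, v_end)))
    stop("hold/step segments must have v_start == v_end")
  structure(
    list(kind = kind, v_start = v_start, v_end = v_end, duration = duration),
    class = "protocol_segment"
  )
}

#' Voltage-clamp command protocol
#'
#' @param name protocol name.
#' @param segments list of [protocol_segment()]s, contiguous in time.
#' @param inter_sweep_interval seconds between sweep starts (> 0).
#' @param junction_potential_correction liquid-junction-potential correction
#'   (mV) already applied to the stored command voltages; metadata only.
#' @return an object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, segments, inter_sweep_interval,
                             junction_potential_correction = 0) {
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "protocol_segment")))
    stop("segments must be a non-empty list of protocol_segment objects")
  if (inter_sweep_interval <= 0) stop("inter_sweep_interval must be > 0")
  p <- structure(
    list(
      name = name,
      segments = segments,
      inter_sweep_interval = inter_sweep_interval,
      junction_potential_correction = junction_potential_correction
    ),
    class = "voltage_protocol"
  )
  stopifnot(protocol_duration(p) > 0)
  p
}

#' Total protocol duration in ms
#' @param protocol a [voltage_protocol()].
#' @return duration in ms.
#' @export
protocol_duration <- function(protocol) {
  sum(vapply(protocol$segments, `[[`, numeric(1), "duration"))
}

#' Segment start/end times of a protocol
#'
#' @param protocol a [voltage_protocol()].
#' @return data.frame with one row per segment: `segment`, `kind`,
#'   `v_start`, `v_end`, `t_start`, `t_end` (ms, 0-based from sweep start).
#' @export
segment_bounds <- function(protocol) {
  dur <- vapply(protocol$segments, `[[`, numeric(1), "duration")
  ends <- cumsum(dur)
  data.frame(
    segment = seq_along(dur),
    kind = vapply(protocol$segments, `[[`, character(1), "kind"),
    v_start = vapply(protocol$segments, `[[`, numeric(1), "v_start"),
    v_end = vapply(protocol$segments, `[[`, numeric(1), "v_end"),
    t_start = c(0, ends[-length(ends)]),
    t_end = ends
  )
}

#' Command voltage at arbitrary times
#'
#' Evaluates the piecewise command waveform. Times beyond the protocol end
#' return the final voltage (the holding level between sweeps).
#'
#' @param protocol a [voltage_protocol()].
#' @param t_ms numeric vector of times in ms from sweep start.
#' @return numeric vector of command voltages (mV).
#' @export
command_voltage <- function(protocol, t_ms) {
  b <- segment_bounds(protocol)
  v <- rep(b$v_end[nrow(b)], length(t_ms))
  for (i in seq_len(nrow(b))) {
    in_seg <- t_ms >= b$t_start[i] & t_ms < b$t_end[i]
    if (!any(in_seg)) next
    if (b$kind[i] == "ramp") {
      frac <- (t_ms[in_seg] - b$t_start[i]) / (b$t_end[i] - b$t_start[i])
      v[in_seg] <- b$v_start[i] + frac * (b$v_end[i] - b$v_start[i])
    } else {
      v[in_seg] <- b$v_end[i]
    }
  }
  v[t_ms < 0] <- b$v_start[1L]
  v
}

#' Standard voltage protocols for hERG, I_CaL and I_NaL
#'
#' Builds the three physiologically motivated command protocols used for
#' potency profiling, with junction-potential-corrected voltages. Each
#' protocol starts with a baseline hold followed by a hyperpolarizing
#' monitoring step used to track input resistance, then the depolarizing
#' sequence and a terminal repolarizing ramp on which (for hERG and I_NaL)
#' drug effects are quantified:
#'
#' * `hERG`: hold -80 mV; -90 mV step (100 ms); -80 mV; +40 mV for 500 ms;
#'   ramp +40 to -80 mV in 100 ms (-1.2 V/s); repeated every 5 s.
#' * `I_CaL`: hold -80 mV; -90 mV step (100 ms); -80 mV; 0 mV for 40 ms;
#'   +30 mV for 200 ms; ramp +30 to -80 mV in 100 ms; every 5 s.
#' * `I_NaL`: hold -95 mV; -120 mV step (200 ms, recovery from
#'   inactivation); -15 mV for 40 ms; +40 mV for 200 ms; ramp +40 to -95 mV
#'   in 100 ms (-1.35 V/s); every 10 s.
#'
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @return a [voltage_protocol()].
#' @export
#' @examples
#' p <- build_standard_protocol("hERG")
#' segment_bounds(p)
build_standard_protocol <- function(current_type) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  seg <- function(...) protocol_segment(...)
  if (current_type == "hERG") {
    segments <- list(
      seg("hold", -80, duration = 100),
      seg("step", -90, duration = 100),
      seg("hold", -80, duration = 100),
      seg("step", 40, duration = 500),
      seg("ramp", 40, -80, duration = 100),
      seg("hold", -80, duration = 200)
    )
    isi <- 5; jp <- 15
  } else if (current_type == "I_CaL") {
    segments <- list(
      seg("hold", -80, duration = 100),
      seg("step", -90, duration = 100),
      seg("hold", -80, duration = 100),
      seg("step", 0, duration = 40),
      seg("step", 30, duration = 200),
      seg("ramp", 30, -80, duration = 100),
      seg("hold", -80, duration = 160)
    )
    isi <- 5; jp <- 17
  } else {
    segments <- list(
      seg("hold", -95, duration = 100),
      seg("step", -120, duration = 200),
      seg("step", -15, duration = 40),
      seg("step", 40, duration = 200),
      seg("ramp", 40, -95, duration = 100),
      seg("hold", -95, duration = 160)
    )
    isi <- 10; jp <- 0
  }
  voltage_protocol(
    name = current_type, segments = segments,
    inter_sweep_interval = isi, junction_potential_correction = jp
  )
}

#' Default digitization interval per current type
#'
#' hERG recordings are digitized at 5 kHz (0.2 ms); I_CaL and I_NaL at
#' 10 kHz (0.1 ms).
#'
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @return sample interval in ms.
#' @export
default_sample_interval <- function(current_type) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  if (current_type == "hERG") 0.2 else 0.1
}

#' Index of the input-resistance monitoring step
#'
#' The hyperpolarizing step (-80 to -90 mV, or -95 to -120 mV for I_NaL)
#' placed before the depolarizing sequence.
#'
#' @param protocol a [voltage_protocol()].
#' @return integer segment index.
#' @export
monitoring_step_index <- function(protocol) {
  b <- segment_bounds(protocol)
  hyp <- which(b$kind == "step" & b$v_end < b$v_start[1L])
  if (!length(hyp)) stop("protocol has no hyperpolarizing monitoring step")
  hyp[1L]
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol> %s: %d segments, %.0f ms, repeated every %g s\n",
    x$name, length(x$segments), protocol_duration(x), x$inter_sweep_interval
  ))
  print(segment_bounds(x))
  invisible(x)
}

# Protocol <-> JSON (list of {kind, v_start_mV, v_end_mV, duration_ms}).
protocol_to_json <- function(protocol) {
  jsonlite::toJSON(list(
    name = protocol$name,
    inter_sweep_interval_s = protocol$inter_sweep_interval,
    junction_potential_correction_mV = protocol$junction_potential_correction,
    segments = lapply(protocol$segments, function(s) list(
      kind = s$kind, v_start_mV = s$v_start, v_end_mV = s$v_end,
      duration_ms = s$duration
    ))
  ), auto_unbox = TRUE, digits = NA)
}

protocol_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  voltage_protocol(
    name = x$name,
    segments = lapply(x$segments, function(s) {
      protocol_segment(s$kind, s$v_start_mV, s$v_end_mV, s$duration_ms)
    }),
    inter_sweep_interval = x$inter_sweep_interval_s,
    junction_potential_correction = x$junction_potential_correction_mV
  )
}
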