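#' Single voltage-clamp sweep
#'
#' @param sample_interval sample interval in ms (> 0).
#' @param current numeric vector of recorded current (pA), one value per
#'   sample, 0-based in time from sweep start.
#' @param sweep_index ordinal position of the sweep within the recording.
#' @param epoch_label `"control"`, `"reference_blocker"`, or
#'   `"drug:<concentration_uM>"` (e.g. `"drug:0.3"`).
#' @param wall_time time of the sweep start on the experiment clock, in
#'   seconds; anchors drug-application chronology.
#' @return an object of class `pp_sweep`.
#' @export
sweep <- function(sample_interval, current, sweep_index, epoch_label,
                  wall_time) {
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  parse_epoch_label(epoch_label)  # validates
  structure(
    list(
      sample_interval = sample_interval,
      current = as.numeric(current),
      sweep_index = as.integer(sweep_index),
      epoch_label = epoch_label,
      wall_time = wall_time
    ),
    class = "pp_sweep"
  )
}

# Split an epoch label into kind + drug concentration (uM, NA unless drug).
parse_epoch_label <- function(label) {
  if (identical(label, "control"))
    return(list(kind = "control", concentration = NA_real_))
  if (identical(label, "reference_blocker"))
    return(list(kind = "reference_blocker", concentration = NA_real_))
  if (grepl("^drug:", label)) {
    conc <- suppressWarnings(as.numeric(sub("^drug:", "", label)))
    if (is.na(conc) || conc <= 0)
      stop("drug epoch label must carry a positive concentration: ", label)
    return(list(kind = "drug", concentration = conc))
  }
  stop("unknown epoch label: ", label)
}

# Sample times (ms) of a sweep.
sweep_times <- function(sw) (seq_along(sw$current) - 1L) * sw$sample_interval

#' One cell's voltage-clamp recording
#'
#' Groups the ordered sweeps of a cell under a single protocol, with the
#' passive membrane properties used as health indicators. Epochs must appear
#' in order control -> drug (one or two concentrations) -> optional
#' reference blocker; every sweep must span the protocol duration to within
#' one sample.
#'
#' @param cell_id cell identifier.
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @param protocol a [voltage_protocol()] shared by all sweeps.
#' @param sweeps list of [sweep()]s in recording order.
#' @param holding_current resting holding current (pA).
#' @param input_resistance resting input resistance (MOhm).
#' @param temperature bath temperature (degrees C).
#' @return an object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, current_type, protocol, sweeps,
                           holding_current = NA_real_,
                           input_resistance = NA_real_,
                           temperature = 37) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  if (!inherits(protocol, "voltage_protocol")) stop("protocol must be a voltage_protocol")
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "pp_sweep")))
    stop("sweeps must be a non-empty list of sweep objects")
  dur <- protocol_duration(protocol)
  for (sw in sweeps) {
    if (abs(length(sw$current) * sw$sample_interval - dur) > sw$sample_interval)
      stop(sprintf(
        "sweep %d: %d samples x %g ms do not span the %g ms protocol",
        sw$sweep_index, length(sw$current), sw$sample_interval, dur
      ))
  }
  kinds <- vapply(sweeps, function(s) parse_epoch_label(s$epoch_label)$kind,
                  character(1))
  order_rank <- c(control = 1L, drug = 2L, reference_blocker = 3L)[kinds]
  if (is.unsorted(order_rank))
    stop("epochs must appear in order control -> drug -> reference_blocker")
  concs <- vapply(sweeps, function(s) parse_epoch_label(s$epoch_label)$concentration,
                  numeric(1))
  drug_concs <- unique(concs[kinds == "drug"])
  if (length(drug_concs) > 2L)
    stop("a cell is exposed to at most two drug concentrations")
  if (length(drug_concs) == 2L && is.unsorted(concs[kinds == "drug"]))
    stop("drug concentrations must be applied in increasing order")
  structure(
    list(
      cell_id = cell_id, current_type = current_type, protocol = protocol,
      sweeps = sweeps, holding_current = holding_current,
      input_resistance = input_resistance, temperature = temperature
    ),
    class = "cell_recording"
  )
}

#' @export
print.cell_recording <- function(x, ...) {
  kinds <- vapply(x$sweeps, function(s) parse_epoch_label(s$epoch_label)$kind,
                  character(1))
  cat(sprintf(
    "<cell_recording> %s (%s): %d sweeps (%s)\n",
    x$cell_id, x$current_type, length(x$sweeps),
    paste(sprintf("%s=%d", names(table(kinds)), as.integer(table(kinds))),
          collapse = ", ")
  ))
  invisible(x)
}

# Sweeps of a given epoch kind (optionally a given drug concentration).
epoch_sweeps <- function(recording, kind, concentration = NULL) {
  keep <- vapply(recording$sweeps, function(s) {
    e <- parse_epoch_label(s$epoch_label)
    e$kind == kind &&
      (is.null(concentration) || isTRUE(all.equal(e$concentration, concentration)))
  }, logical(1))
  recording$sweeps[keep]
}

#' Measurement window for drug-effect quantification
#'
#' Names the protocol segment and time offsets (ms, relative to the segment
#' start) over which the drug-sensitive current is quantified, together with
#' the summary statistic and the polarity of the current of interest.
#'
#' @param segment_index 1-based protocol segment index.
#' @param t_offset_start,t_offset_end window bounds in ms relative to the
#'   segment start; `t_offset_end = NULL` means the segment end.
#' @param statistic `"peak_magnitude"` (extremum of the stated polarity) or
#'   `"mean"` (time average).
#' @param direction `"outward"` (positive, e.g. the hERG tail) or
#'   `"inward"` (negative, I_CaL / I_NaL).
#' @return an object of class `measurement_window`.
#' @export
measurement_window <- function(segment_index, t_offset_start = 0,
                               t_offset_end = NULL,
                               statistic = c("peak_magnitude", "mean"),
                               direction = c("outward", "inward")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  if (!is.null(t_offset_end) && t_offset_end <= t_offset_start)
    stop("t_offset_end must exceed t_offset_start")
  structure(
    list(
      segment_index = as.integer(segment_index),
      t_offset_start = t_offset_start, t_offset_end = t_offset_end,
      statistic = statistic, direction = direction
    ),
    class = "measurement_window"
  )
}

#' Default quantification window per current type
#'
#' hERG: peak outward tail current on the terminal ramp. I_CaL: peak inward
#' current during the 0 mV step (after isolation). I_NaL: mean inward
#' current over the middle 50% of the terminal ramp.
#'
#' @param current_type `"hERG"`, `"I_CaL"` or `"I_NaL"`.
#' @param protocol the protocol the window refers to; defaults to the
#'   standard protocol for `current_type`.
#' @return a [measurement_window()].
#' @export
default_measurement_window <- function(current_type,
                                       protocol = build_standard_protocol(current_type)) {
  current_type <- match.arg(current_type, c("hERG", "I_CaL", "I_NaL"))
  b <- segment_bounds(protocol)
  if (current_type == "hERG") {
    ramp <- which(b$kind == "ramp")[1L]
    measurement_window(ramp, statistic = "peak_magnitude", direction = "outward")
  } else if (current_type == "I_CaL") {
    step0 <- which(b$kind == "step" & b$v_end == 0)[1L]
    if (is.na(step0)) stop("protocol has no 0 mV step")
    measurement_window(step0, statistic = "peak_magnitude", direction = "inward")
  } else {
    ramp <- which(b$kind == "ramp")[1L]
    dur <- b$t_end[ramp] - b$t_start[ramp]
    measurement_window(ramp, t_offset_start = 0.25 * dur,
                       t_offset_end = 0.75 * dur,
                       statistic = "mean", direction = "inward")
  }
}

#' Write a cell recording to disk
#'
#' CSV dialect: `#`-prefixed header lines (`cell_id`, `current_type`,
#' `input_resistance_MOhm`, `holding_current_pA`, `temperature_C`, and the
#' protocol as one-line JSON), then long-format columns
#' `sweep_index,epoch_label,wall_time_s,time_ms,current_pA`.
#'
#' @param recording a [cell_recording()].
#' @param path output file path.
#' @param dialect only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, dialect = "csv") {
  if (!identical(dialect, "csv"))
    stop("unsupported recording dialect: ", dialect)
  header <- c(
    sprintf("# cell_id=%s", recording$cell_id),
    sprintf("# current_type=%s", recording$current_type),
    sprintf("# input_resistance_MOhm=%s",
            format(recording$input_resistance, digits = 17)),
    sprintf("# holding_current_pA=%s",
            format(recording$holding_current, digits = 17)),
    sprintf("# temperature_C=%s", format(recording$temperature, digits = 17)),
    sprintf("# protocol=%s", as.character(protocol_to_json(recording$protocol)))
  )
  tabs <- lapply(recording$sweeps, function(sw) {
    data.table::data.table(
      sweep_index = sw$sweep_index,
      epoch_label = sw$epoch_label,
      wall_time_s = sw$wall_time,
      time_ms = sweep_times(sw),
      current_pA = sw$current
    )
  })
  dt <- data.table::rbindlist(tabs)
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a cell recording from disk
#'
#' Counterpart of [write_recording()]; validates the header, the epoch
#' labels and the per-sweep sample counts, and refuses silently truncated
#' sweeps (a sweep whose samples do not span the protocol).
#'
#' @param path file written by [write_recording()].
#' @param dialect only `"csv"` is supported.
#' @return a [cell_recording()].
#' @export
read_recording <- function(path, dialect = "csv") {
  if (!identical(dialect, "csv"))
    stop("unsupported recording dialect: ", dialect)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) stop("malformed header: missing field '", key, "'")
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  protocol <- protocol_from_json(get_field("protocol"))
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE)
  need <- c("sweep_index", "epoch_label", "wall_time_s", "time_ms", "current_pA")
  if (!all(need %in% names(dt)))
    stop("malformed recording table: expected columns ", paste(need, collapse = ", "))
  dur <- protocol_duration(protocol)
  sweeps <- lapply(split(dt, by = "sweep_index", sorted = TRUE), function(d) {
    dt_ms <- if (nrow(d) > 1L) d$time_ms[2L] - d$time_ms[1L] else dur
    if (abs(nrow(d) * dt_ms - dur) > dt_ms)
      stop(sprintf("sweep %d is truncated: %d samples x %g ms vs %g ms protocol",
                   d$sweep_index[1L], nrow(d), dt_ms, dur))
    sweep(
      sample_interval = dt_ms, current = d$current_pA,
      sweep_index = d$sweep_index[1L], epoch_label = d$epoch_label[1L],
      wall_time = d$wall_time_s[1L]
    )
  })
  sweeps <- sweeps[order(vapply(sweeps, `[[`, integer(1), "sweep_index"))]
  cell_recording(
    cell_id = get_field("cell_id"),
    current_type = get_field("current_type"),
    protocol = protocol,
    sweeps = unname(sweeps),
    holding_current = as.numeric(get_field("holding_current_pA")),
    input_resistance = as.numeric(get_field("input_resistance_MOhm")),
    temperature = as.numeric(get_field("temperature_C"))
  )
}
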