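#' Paced action-potential train
#'
#' Continuous microelectrode membrane-potential recording from a paced
#' ventricular trabecula, with the stimulus times and pacing rate.
#'
#' @param sample_interval sample interval in ms (20 kHz recordings use
#'   0.05 ms).
#' @param voltage membrane potential samples (mV).
#' @param stimulus_times stimulus onset times (ms), strictly increasing and
#'   consistent with `pacing_rate` to within 1%.
#' @param pacing_rate pacing rate in Hz.
#' @param tissue_id trabecula identifier.
#' @param epoch_label `"vehicle"` or `"drug:<name@concentration>"`.
#' @return object of class `ap_train`.
#' @export
ap_train <- function(sample_interval, voltage, stimulus_times, pacing_rate,
                     tissue_id = "tissue", epoch_label = "vehicle") {
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (length(stimulus_times) < 1L) stop("at least one stimulus is required")
  if (is.unsorted(stimulus_times, strictly = TRUE))
    stop("stimulus_times must be strictly increasing")
  if (length(stimulus_times) > 1L) {
    iv <- diff(stimulus_times)
    expected <- 1000 / pacing_rate
    if (any(abs(iv - expected) > 0.01 * expected))
      stop("stimulus intervals inconsistent with pacing_rate (>1% deviation)")
  }
  structure(
    list(
      sample_interval = sample_interval, voltage = as.numeric(voltage),
      stimulus_times = stimulus_times, pacing_rate = pacing_rate,
      tissue_id = tissue_id, epoch_label = epoch_label
    ),
    class = "ap_train"
  )
}

train_times <- function(train) (seq_along(train$voltage) - 1L) * train$sample_interval

#' APD at a repolarization percentage for one beat
#'
#' Time from AP onset to the first downward crossing of the level
#' `peak - (percent/100) * amplitude` during repolarization, with linear
#' interpolation between samples. Onset is the upstroke crossing of 10% of
#' the amplitude above the resting potential. Later re-depolarizations
#' above the level (EAD-like humps) do not move the crossing; they are
#' flagged by [detect_beats()].
#'
#' @param t sample times (ms) of the beat segment.
#' @param v voltage samples (mV) of the beat segment.
#' @param percent repolarization percentage in (0, 100).
#' @param resting,peak resting and peak potential (mV); computed from the
#'   segment when omitted.
#' @return APD in ms, or `NA` when the level is never reached within the
#'   segment.
#' @export
#' @examples
#' # instant rise, linear repolarization over 300 ms: APD30 = 90 ms
apd_at_percent <- function(t, v, percent, resting = NULL, peak = NULL) {
  if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
  resting <- resting %||% v[1L]
  i_peak <- which.max(v)
  peak <- peak %||% v[i_peak]
  amp <- peak - resting
  if (amp <= 0) stop("non-depolarizing beat: amplitude <= 0")
  onset <- first_crossing_time(t, v, resting + 0.1 * amp, "up",
                               idx_end = i_peak)
  if (is.na(onset)) onset <- t[1L]
  level <- peak - (percent / 100) * amp
  crossing <- first_crossing_time(t, v, level, "down", idx_start = i_peak)
  if (is.na(crossing)) return(NA_real_)
  crossing - onset
}

#' Segment a paced train into beats and extract per-beat landmarks
#'
#' One beat per stimulus. The resting potential is the mean voltage over
#' the `rest_window_ms` before the stimulus; the peak is the maximal
#' voltage before the next stimulus. A beat is captured when the voltage
#' rises at least `capture_dv` mV above rest within `capture_window_ms` of
#' the stimulus; uncaptured beats carry `NA` landmarks.
#'
#' @param train an [ap_train()].
#' @param capture_dv capture criterion (mV above rest), default 40.
#' @param capture_window_ms window after the stimulus in which the
#'   depolarization must occur.
#' @param rest_window_ms pre-stimulus window for the resting potential.
#' @return data.frame with one row per stimulus: `stim_time`,
#'   `resting_potential`, `peak_potential`, `amplitude`, `apd30`, `apd50`,
#'   `apd90`, `captured`, `repolarization_flag` (TRUE when the voltage
#'   re-crosses the APD90 level after the first crossing).
#' @export
detect_beats <- function(train, capture_dv = 40, capture_window_ms = 50,
                         rest_window_ms = 20) {
  t <- train_times(train)
  v <- train$voltage
  stim <- train$stimulus_times
  t_end <- t[length(t)] + train$sample_interval
  rows <- lapply(seq_along(stim), function(i) {
    s <- stim[i]
    e <- if (i < length(stim)) stim[i + 1L] else t_end
    pre <- v[t >= s - rest_window_ms & t < s]
    rest <- if (length(pre)) mean(pre) else v[max(1L, which(t >= s)[1L])]
    sel <- which(t >= s & t < e)
    vb <- v[sel]; tb <- t[sel]
    i_peak <- which.max(vb)
    peak <- vb[i_peak]
    cap_sel <- tb <= s + capture_window_ms
    captured <- any(vb[cap_sel] >= rest + capture_dv)
    if (!captured) {
      return(data.frame(
        stim_time = s, resting_potential = rest, peak_potential = peak,
        amplitude = NA_real_, apd30 = NA_real_, apd50 = NA_real_,
        apd90 = NA_real_, captured = FALSE, repolarization_flag = FALSE
      ))
    }
    apd <- vapply(c(30, 50, 90), function(p) {
      apd_at_percent(tb, vb, p, resting = rest, peak = peak)
    }, numeric(1))
    # EAD-like flag: voltage rises back above the APD90 level after crossing
    lvl90 <- peak - 0.9 * (peak - rest)
    flag <- FALSE
    if (!is.na(apd[3L])) {
      after <- which(tb > tb[i_peak] & vb <= lvl90)
      if (length(after)) {
        flag <- any(vb[after[1L]:length(vb)] > lvl90 + 1)  # 1 mV hysteresis
      }
    }
    data.frame(
      stim_time = s, resting_potential = rest, peak_potential = peak,
      amplitude = peak - rest, apd30 = apd[1L], apd50 = apd[2L],
      apd90 = apd[3L], captured = TRUE, repolarization_flag = flag
    )
  })
  do.call(rbind, rows)
}

#' AP triangulation
#'
#' `APD90 - APD30`: lengthening of late relative to early repolarization, a
#' signature of hERG block.
#'
#' @param apd90,apd30 durations in ms (scalars or equal-length vectors).
#' @return triangulation in ms.
#' @export
triangulation <- function(apd90, apd30) apd90 - apd30

#' Short-term variability of APD90
#'
#' Poincare-plot statistic of beat-to-beat repolarization variability:
#' `STV = sum(|APD90[n+1] - APD90[n]|) / (n_diff * sqrt(2))`, by default
#' over 30 successive differences (31 consecutive beats).
#'
#' @param apd90 APD90 series in ms, at least `n_diff + 1` values; when
#'   longer, the trailing `n_diff + 1` values are used.
#' @param n_diff number of successive differences (default 30).
#' @return STV in ms.
#' @export
#' @examples
#' stv(rep(300, 31))               # 0
#' stv(rep(c(300, 310), 16)[1:31]) # 300 / (30 * sqrt(2))
stv <- function(apd90, n_diff = 30L) {
  if (anyNA(apd90)) stop("apd90 series contains NA")
  if (length(apd90) < n_diff + 1L)
    stop("need at least ", n_diff + 1L, " APD90 values for ", n_diff,
         " successive differences")
  x <- utils::tail(apd90, n_diff + 1L)
  sum(abs(diff(x))) / (n_diff * sqrt(2))
}

#' Per-epoch AP feature summary
#'
#' Means of APD30/50/90 and amplitude over `n_beats` consecutive captured
#' beats (the trailing ones, i.e. at steady state), triangulation of the
#' means, and STV over the trailing `n_beats + 1` captured beats when
#' available.
#'
#' @param train an [ap_train()].
#' @param beats precomputed [detect_beats()] output.
#' @param n_beats number of beats averaged (default 30).
#' @return one-row data.frame of class `ap_feature_summary`: `tissue_id`,
#'   `epoch_label`, `pacing_rate`, `mean_apd30/50/90`, `triangulation`,
#'   `stv`, `mean_amplitude`, `n_beats`, `excitability_loss`.
#' @export
summarize_ap_train <- function(train, beats = detect_beats(train),
                               n_beats = 30L) {
  cap <- beats[beats$captured & !is.na(beats$apd90), , drop = FALSE]
  if (nrow(cap) < n_beats)
    stop("only ", nrow(cap), " captured beats; ", n_beats, " required")
  use <- utils::tail(cap, n_beats)
  stv_val <- if (nrow(cap) >= n_beats + 1L) {
    stv(utils::tail(cap$apd90, n_beats + 1L), n_diff = n_beats)
  } else NA_real_
  out <- data.frame(
    tissue_id = train$tissue_id,
    epoch_label = train$epoch_label,
    pacing_rate = train$pacing_rate,
    mean_apd30 = mean(use$apd30),
    mean_apd50 = mean(use$apd50),
    mean_apd90 = mean(use$apd90),
    triangulation = mean(use$apd90) - mean(use$apd30),
    stv = stv_val,
    mean_amplitude = mean(use$amplitude),
    n_beats = as.integer(n_beats),
    excitability_loss = any(!beats$captured),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ap_feature_summary", class(out))
  out
}

#' Percent change of an AP parameter versus vehicle
#'
#' `100 * (drug - vehicle) / vehicle` for the named summary parameter;
#' requires matching tissue and pacing rate.
#'
#' @param summary_drug,summary_vehicle [summarize_ap_train()] rows.
#' @param parameter one of `"apd30"`, `"apd50"`, `"apd90"`,
#'   `"triangulation"`, `"stv"`, `"amplitude"`.
#' @return signed percent change.
#' @export
percent_change <- function(summary_drug, summary_vehicle, parameter) {
  col <- switch(parameter,
    apd30 = "mean_apd30", apd50 = "mean_apd50", apd90 = "mean_apd90",
    triangulation = "triangulation", stv = "stv",
    amplitude = "mean_amplitude",
    stop("unknown AP parameter: ", parameter)
  )
  if (!identical(summary_drug$tissue_id, summary_vehicle$tissue_id))
    stop("summaries come from different tissues")
  if (!isTRUE(all.equal(summary_drug$pacing_rate, summary_vehicle$pacing_rate)))
    stop("summaries come from different pacing rates")
  base <- summary_vehicle[[col]]
  if (!is.finite(base) || base == 0) stop("vehicle value for ", parameter, " is zero")
  100 * (summary_drug[[col]] - base) / base
}

#' Change-over-baseline thresholds
#'
#' Percent-change thresholds per parameter and pacing rate, above which a
#' drug effect is called (shipped as a versioned JSON resource): APD30
#' 12.0/12.1, APD50 9.1/9.7, APD90 6.9/7.5, triangulation 9.0/10.2, STV
#' 102.6/164.3, at 1/2 Hz.
#'
#' @return nested list `thresholds[[parameter]][[as.character(rate)]]`.
#' @export
ap_change_thresholds <- function() {
  path <- system.file("extdata", "ap_change_thresholds.json",
                      package = "patchpharm", mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = FALSE)$thresholds
}

#' Classify a percent change against its threshold
#'
#' The comparison uses the absolute value of the signed percent change.
#'
#' @param pct signed percent change.
#' @param parameter `"apd30"`, `"apd50"`, `"apd90"`, `"triangulation"` or
#'   `"stv"`.
#' @param pacing_rate pacing rate in Hz (1 or 2).
#' @param thresholds thresholds table from [ap_change_thresholds()].
#' @return logical: does the change exceed the threshold.
#' @export
classify_change <- function(pct, parameter, pacing_rate,
                            thresholds = ap_change_thresholds()) {
  par_tab <- thresholds[[parameter]]
  if (is.null(par_tab)) stop("no threshold for parameter: ", parameter)
  thr <- par_tab[[format(pacing_rate)]]
  if (is.null(thr)) stop("no threshold for pacing rate ", pacing_rate, " Hz")
  abs(pct) > thr
}

#' Tissue-level quality control
#'
#' A trabecula enters the dataset only when its baseline APD90 lies in
#' [200, 450] ms and none of the metadata exclusion flags (perfusion
#' interruption, absent/unstable baseline APs, inadequate drug exposure)
#' are set. All violated rules are reported.
#'
#' @param baseline_summary [summarize_ap_train()] of the vehicle epoch.
#' @param metadata list with logical elements `perfusion_interrupted`,
#'   `unstable_baseline`, `inadequate_exposure` (missing = FALSE).
#' @param apd90_bounds inclusion bounds for the baseline APD90 (ms).
#' @return list with `keep` (logical) and `reasons` (character vector).
#' @export
qc_tissue <- function(baseline_summary, metadata = list(),
                      apd90_bounds = c(200, 450)) {
  reasons <- character(0)
  apd90 <- baseline_summary$mean_apd90
  if (apd90 < apd90_bounds[1L])
    reasons <- c(reasons, sprintf("baseline APD90 %.0f ms below %g ms",
                                  apd90, apd90_bounds[1L]))
  if (apd90 > apd90_bounds[2L])
    reasons <- c(reasons, sprintf("baseline APD90 %.0f ms above %g ms",
                                  apd90, apd90_bounds[2L]))
  if (isTRUE(metadata$perfusion_interrupted))
    reasons <- c(reasons, "perfusion/oxygenation interrupted")
  if (isTRUE(metadata$unstable_baseline))
    reasons <- c(reasons, "absent or unstable baseline APs")
  if (isTRUE(metadata$inadequate_exposure))
    reasons <- c(reasons, "drug exposure time not adequate")
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Write / read an AP train
#'
#' CSV with columns `time_ms,voltage_mV`, plus a JSON sidecar
#' (`<path>.json`) carrying `stimulus_times_ms`, `pacing_rate_hz`,
#' `tissue_id`, `epoch_label` and `sample_interval_ms`.
#'
#' @param train an [ap_train()].
#' @param path CSV path (sidecar written next to it).
#' @return `path` invisibly ([write_ap_train()]); an [ap_train()]
#'   ([read_ap_train()]).
#' @export
write_ap_train <- function(train, path) {
  data.table::fwrite(
    data.table::data.table(time_ms = train_times(train),
                           voltage_mV = train$voltage),
    path
  )
  jsonlite::write_json(
    list(
      stimulus_times_ms = train$stimulus_times,
      pacing_rate_hz = train$pacing_rate,
      tissue_id = train$tissue_id,
      epoch_label = train$epoch_label,
      sample_interval_ms = train$sample_interval
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ap_train
#' @export
read_ap_train <- function(path) {
  dt <- data.table::fread(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  ap_train(
    sample_interval = meta$sample_interval_ms,
    voltage = dt$voltage_mV,
    stimulus_times = meta$stimulus_times_ms,
    pacing_rate = meta$pacing_rate_hz,
    tissue_id = meta$tissue_id,
    epoch_label = meta$epoch_label
  )
}
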