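#' Materialise a run configuration
#'
#' Loads a YAML/JSON config file (or accepts a list), fills in every
#' default explicitly, and returns the merged configuration so that every
#' tolerance and seed used by a run is recorded. The effective config is
#' written alongside the outputs by the `cmd_*` functions.
#'
#' @param config path to a YAML or JSON file, or a named list.
#' @return list of class `run_config` with all defaults materialised.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- list(
    input_dir = ".",
    output_dir = ".",
    drug = "drug",
    n_traces = 10L,
    stability_n = 20L,
    slope_tolerance = 1,
    smooth_ms = 1,
    ci_method = "bootstrap",
    n_boot = 1000L,
    seed = 1L,
    n_beats = 30L,
    apd90_bounds = c(200, 450)
  )
  merged <- utils::modifyList(defaults, config)
  class(merged) <- c("run_config", "list")
  merged
}

write_effective_config <- function(config, out_dir) {
  plain <- lapply(unclass(config), function(x) {
    if (is.object(x) && !is.data.frame(x)) unclass(x) else x
  })
  jsonlite::write_json(plain, file.path(out_dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_lines <- function(out_dir, lines, file = "run_log.txt") {
  cat(lines, file = file.path(out_dir, file), sep = "\n", append = TRUE)
}

#' Generate simulated fixtures on disk
#'
#' Writes one recording file per simulated cell (and optionally AP trains
#' per drug mode) plus a ground-truth JSON so downstream stages can be
#' verified against the programmed parameters. Byte-identical across reruns
#' with the same config.
#'
#' @param config a [run_config()]; honoured fields: `output_dir`, `seed`,
#'   and `vc_spec` / `ap_modes` (a [voltage_clamp_sim_spec()] and a
#'   character vector of AP drug modes).
#' @return invisibly, list with the written file names.
#' @export
cmd_simulate <- function(config = run_config()) {
  config <- run_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- config$vc_spec %||% voltage_clamp_sim_spec(seed = config$seed)
  files <- character(0)
  truth <- list(
    current_type = spec$current_type, true_ic50 = spec$true_ic50,
    true_n_h = spec$true_n_h, concentrations = spec$concentrations,
    n_cells_per_concentration = spec$n_cells_per_concentration
  )
  k <- 0L
  for (conc in spec$concentrations) {
    for (cell in seq_len(spec$n_cells_per_concentration)) {
      k <- k + 1L
      id <- sprintf("sim_%03d", k)
      rec <- simulate_voltage_clamp_cell(spec, conc, cell_id = id,
                                         seed = spec$seed + k)
      f <- file.path(out, paste0(id, ".csv"))
      write_recording(rec, f)
      files <- c(files, f)
    }
  }
  ap_files <- character(0)
  for (mode in (config$ap_modes %||% character(0))) {
    sp <- ap_sim_spec(drug_mode = mode, seed = config$seed,
                      tissue_id = "sim_tissue")
    tr <- simulate_ap_train(sp)
    f <- file.path(out, paste0("ap_", mode, ".csv"))
    write_ap_train(tr, f)
    ap_files <- c(ap_files, f)
  }
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_effective_config(config, out)
  invisible(list(recordings = files, ap_trains = ap_files,
                 ground_truth = file.path(out, "ground_truth.json")))
}

#' Run the isolation stage over a directory of recordings
#'
#' Reads every recording in `input_dir`, computes per-cell fractional
#' inhibition with the configured windows and stability tolerances, and
#' writes `fractional_inhibition.csv`
#' (`drug,current_type,cell_id,concentration_uM,fraction_inhibited,
#' n_control,n_drug`). Cells failing the stability gate (or erroring) are
#' skipped and logged with their reason; an unreadable input is fatal.
#'
#' @param config a [run_config()].
#' @return invisibly, list with the results table, the exclusion log and
#'   the output path.
#' @export
cmd_isolate <- function(config = run_config()) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  paths <- paths[!grepl("^ap_|fractional_inhibition|curves|fits|ratios",
                        basename(paths))]
  if (!length(paths)) stop("no recording files found in ", config$input_dir)
  rows <- list(); excluded <- character(0)
  for (p in paths) {
    rec <- read_recording(p)  # unreadable input is fatal by design
    res <- tryCatch(
      fractional_inhibition(
        rec,
        n_traces = config$n_traces,
        stability_n = config$stability_n,
        slope_tolerance = config$slope_tolerance,
        smooth_ms = config$smooth_ms
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      excluded <- c(excluded, sprintf("EXCLUDED %s: %s", rec$cell_id, res))
    } else {
      res$drug <- config$drug
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stop("all cells were excluded; nothing to report")
  tab <- tab[, c("drug", "current_type", "cell_id", "concentration_uM",
                 "fraction_inhibited", "n_control", "n_drug")]
  out_file <- file.path(config$output_dir, "fractional_inhibition.csv")
  data.table::fwrite(tab, out_file)
  log_lines(config$output_dir, c(
    sprintf("isolate: %d cells analyzed, %d excluded", length(rows),
            length(excluded)),
    excluded
  ))
  write_effective_config(config, config$output_dir)
  invisible(list(table = tab, excluded = excluded, path = out_file))
}

#' Run the potency-fitting stage
#'
#' Fits one constrained Hill model per drug x current from a fractional
#' inhibition table, writes the fits as JSON, a tidy predicted-curve CSV
#' for plotting, and (when `printed_ic50s` is supplied in the config) a
#' selectivity-ratio table computed from printed IC50s without refitting.
#'
#' @param config a [run_config()]; `points_file` names the input CSV
#'   (default `fractional_inhibition.csv` in `input_dir`). Optional
#'   `printed_ic50s`: data.frame with columns `label`, `ic50_numerator`,
#'   `unit_numerator`, `ic50_denominator`, `unit_denominator`, `rounding`.
#' @return invisibly, list with the fits, the ratio table and the output
#'   paths.
#' @export
cmd_fit <- function(config = run_config()) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list(); curves <- list(); failures <- character(0)
  points_file <- config$points_file %||%
    file.path(config$input_dir, "fractional_inhibition.csv")
  if (file.exists(points_file)) {
    pts <- data.table::fread(points_file)
    if (!nrow(pts)) stop("points file is empty: ", points_file)
    for (key in split(pts, by = c("drug", "current_type"))) {
      df <- as.data.frame(key)
      fit <- tryCatch(
        hill_ci(fit_hill(df), method = config$ci_method,
                n_boot = config$n_boot, seed = config$seed),
        error = function(e) conditionMessage(e)
      )
      id <- sprintf("%s_%s", df$drug[1L], df$current_type[1L])
      if (is.character(fit)) {
        failures <- c(failures, sprintf("FIT FAILED %s: %s", id, fit))
        next
      }
      fits[[id]] <- list(
        drug = fit$drug, current_type = fit$current_type,
        ic50_uM = fit$ic50, ic50_ci95 = fit$ic50_ci95,
        n_h = fit$n_h, n_h_ci95 = fit$n_h_ci95,
        ci_method = fit$ci_method, n_points = fit$n_points
      )
      cc <- exp(seq(log(min(df$concentration_uM) / 10),
                    log(max(df$concentration_uM) * 10), length.out = 100))
      curves[[id]] <- data.frame(
        drug = fit$drug, current_type = fit$current_type,
        concentration_uM = cc,
        predicted_inhibition = hill_inhibition(cc, fit$ic50, fit$n_h)
      )
    }
    jsonlite::write_json(fits, file.path(config$output_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    data.table::fwrite(do.call(rbind, curves),
                       file.path(config$output_dir, "curves.csv"))
  } else if (is.null(config$printed_ic50s)) {
    stop("points file not found: ", points_file)
  }
  ratios <- NULL
  if (!is.null(config$printed_ic50s)) {
    pr <- as.data.frame(config$printed_ic50s)
    ratios <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
      r <- selectivity_ratio(
        pr$ic50_numerator[i], pr$ic50_denominator[i],
        rounding = pr$rounding[i] %||% "nearest_int",
        unit_numerator = pr$unit_numerator[i],
        unit_denominator = pr$unit_denominator[i]
      )
      data.frame(label = pr$label[i], ratio = r$ratio, raw_ratio = r$raw_ratio)
    }))
    data.table::fwrite(ratios, file.path(config$output_dir, "ratios.csv"))
  }
  log_lines(config$output_dir, c(
    sprintf("fit: %d fits, %d failures", length(fits), length(failures)),
    failures
  ))
  write_effective_config(config, config$output_dir)
  invisible(list(fits = fits, ratios = ratios, failures = failures,
                 output_dir = config$output_dir))
}

#' Run the AP pharmacology stage
#'
#' Reads AP trains (CSV + JSON sidecars, one vehicle epoch plus drug
#' epochs per tissue), applies tissue QC to the vehicle epoch, summarises
#' each epoch over `n_beats` beats, and writes per-epoch summaries and the
#' percent changes versus vehicle with their threshold-exceedance flags.
#' Tissues failing QC, or lacking a vehicle epoch, are excluded with
#' logged reasons.
#'
#' @param config a [run_config()]; `train_files` optionally names the CSVs
#'   (default: every `ap_*.csv` in `input_dir`).
#' @return invisibly, list with `summaries`, `changes` and `excluded`.
#' @export
cmd_ap <- function(config = run_config()) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- config$train_files %||%
    list.files(config$input_dir, pattern = "^ap_.*\\.csv$", full.names = TRUE)
  files <- files[!grepl("\\.json$", files)]
  if (!length(files)) stop("no AP train files found")
  trains <- lapply(files, read_ap_train)
  tissues <- split(trains, vapply(trains, `[[`, character(1), "tissue_id"))
  summaries <- list(); changes <- list(); excluded <- character(0)
  thresholds <- ap_change_thresholds()
  for (tid in names(tissues)) {
    tt <- tissues[[tid]]
    labels <- vapply(tt, `[[`, character(1), "epoch_label")
    if (!"vehicle" %in% labels) {
      excluded <- c(excluded, sprintf("EXCLUDED %s: no vehicle epoch", tid))
      next
    }
    veh <- summarize_ap_train(tt[[which(labels == "vehicle")[1L]]],
                              n_beats = config$n_beats)
    qc <- qc_tissue(veh, metadata = config$qc_metadata %||% list(),
                    apd90_bounds = config$apd90_bounds)
    if (!qc$keep) {
      excluded <- c(excluded, sprintf("EXCLUDED %s: %s", tid,
                                      paste(qc$reasons, collapse = "; ")))
      next
    }
    summaries[[length(summaries) + 1L]] <- veh
    for (i in which(labels != "vehicle")) {
      sm <- summarize_ap_train(tt[[i]], n_beats = config$n_beats)
      summaries[[length(summaries) + 1L]] <- sm
      for (par in c("apd30", "apd50", "apd90", "triangulation", "stv")) {
        pct <- percent_change(sm, veh, par)
        changes[[length(changes) + 1L]] <- data.frame(
          tissue_id = tid, epoch_label = sm$epoch_label,
          pacing_rate = sm$pacing_rate, parameter = par,
          percent_change = pct,
          exceeds_threshold = classify_change(pct, par, sm$pacing_rate,
                                              thresholds)
        )
      }
    }
  }
  if (!length(summaries)) stop("all tissues were excluded")
  sum_tab <- do.call(rbind, summaries)
  chg_tab <- do.call(rbind, changes)
  data.table::fwrite(sum_tab, file.path(config$output_dir, "ap_summaries.csv"))
  data.table::fwrite(chg_tab, file.path(config$output_dir, "ap_changes.csv"))
  log_lines(config$output_dir, c(
    sprintf("ap: %d epochs summarised, %d tissues excluded",
            nrow(sum_tab), length(excluded)),
    excluded
  ))
  write_effective_config(config, config$output_dir)
  invisible(list(summaries = sum_tab, changes = chg_tab, excluded = excluded))
}
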