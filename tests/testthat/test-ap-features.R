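# AP landmark extraction, repolarization statistics, QC and thresholds.

test_that("APD at percent follows linear-repolarization geometry", {
  tr <- make_linear_ap_train(repol_ms = 300)
  beats <- detect_beats(tr)
  expect_true(all(beats$captured))
  # instant rise, linear fall over 300 ms: APDx = 3 * x ms
  expect_equal(beats$apd30, rep(90, 3), tolerance = 1e-3)
  expect_equal(beats$apd50, rep(150, 3), tolerance = 1e-3)
  expect_equal(beats$apd90, rep(270, 3), tolerance = 1e-3)
  expect_true(all(beats$apd30 <= beats$apd50 & beats$apd50 <= beats$apd90))
})

test_that("APD is invariant to uniform voltage offset and scaling", {
  tr <- make_linear_ap_train(repol_ms = 240)
  t <- (seq_along(tr$voltage) - 1) * tr$sample_interval
  base <- apd_at_percent(t, tr$voltage, 50)
  expect_equal(apd_at_percent(t, tr$voltage + 17, 50), base)
  expect_equal(apd_at_percent(t, (tr$voltage + 85) * 2.5 - 85, 50), base)
  expect_error(apd_at_percent(t, tr$voltage, 0), "percent")
})

test_that("beat detection flags uncaptured stimuli and measures amplitude", {
  # every stimulus subthreshold: flat trace
  flat <- ap_train(0.05, rep(-85, 20000 * 3),
                   stimulus_times = c(100, 1100, 2100), pacing_rate = 1)
  b <- detect_beats(flat)
  expect_equal(sum(b$captured), 0)
  expect_true(all(is.na(b$apd90)))

  sp <- ap_sim_spec(jitter_sd = 0, rest = -85, peak = 35, seed = 1)
  tr <- simulate_ap_train(sp)
  b2 <- detect_beats(tr)
  expect_equal(sum(b2$captured), sp$n_beats)
  # programmed amplitude 120 mV, recovered within half a sample's rise
  expect_equal(mean(b2$amplitude), 120, tolerance = 0.01)
  expect_error(detect_beats(ap_train(0.05, rep(-85, 100),
                                     numeric(0), 1)), "stimulus")
})

test_that("triangulation is APD90 minus APD30", {
  expect_equal(triangulation(270, 90), 180)
  expect_equal(triangulation(250, 250), 0)
  sp <- ap_sim_spec(jitter_sd = 0, drug_mode = "mixed_block", seed = 1)
  tr_drug <- summarize_ap_train(simulate_ap_train(sp))
  tr_veh <- summarize_ap_train(simulate_ap_train(ap_sim_spec(jitter_sd = 0)))
  # early-phase shortening increases triangulation
  expect_gt(tr_drug$triangulation, tr_veh$triangulation)
})

test_that("STV matches the direct-summation oracle and its closed forms", {
  expect_equal(stv(rep(300, 31)), 0)
  alt <- rep(c(300, 310), length.out = 31)
  expect_equal(stv(alt), 300 / (30 * sqrt(2)))
  expect_equal(stv(alt), 7.071, tolerance = 1e-3)

  # exact agreement with direct summation on random integer sequences
  set.seed(42)
  for (i in 1:10) {
    x <- sample(250:350, 31, replace = TRUE)
    oracle <- sum(abs(x[-1] - x[-31])) / (30 * sqrt(2))
    expect_identical(stv(x), oracle)
  }
  # linear scaling with jitter amplitude
  x <- rnorm(31, 300, 5)
  centered <- x - mean(x)
  expect_equal(stv(mean(x) + 3 * centered), 3 * stv(x), tolerance = 1e-9)
  expect_error(stv(rep(300, 30)), "31")
})

test_that("Monte Carlo STV under Gaussian jitter matches sigma * sqrt(2/pi)", {
  sigma <- 5
  vals <- patchpharm:::with_local_seed(99, {
    replicate(10000, stv(rnorm(31, 300, sigma)))
  })
  expect_equal(mean(vals), sigma * sqrt(2 / pi), tolerance = 0.02)
})

test_that("percent changes versus vehicle are signed and validated", {
  veh <- summarize_ap_train(simulate_ap_train(ap_sim_spec(jitter_sd = 0)))
  expect_equal(percent_change(veh, veh, "apd90"), 0)
  drug <- veh
  drug$mean_apd90 <- veh$mean_apd90 * 1.8
  expect_equal(percent_change(drug, veh, "apd90"), 80)
  drug$mean_apd90 <- veh$mean_apd90 * 0.5
  expect_equal(percent_change(drug, veh, "apd90"), -50)
  other <- veh; other$tissue_id <- "other"
  expect_error(percent_change(other, veh, "apd90"), "tissues")
  expect_error(percent_change(drug, veh, "upstroke"), "unknown")
})

test_that("threshold classification matches the published table exactly", {
  thr <- ap_change_thresholds()
  expect_equal(thr$apd30[["1"]], 12.0)
  expect_equal(thr$apd30[["2"]], 12.1)
  expect_equal(thr$apd50[["1"]], 9.1)
  expect_equal(thr$apd50[["2"]], 9.7)
  expect_equal(thr$apd90[["1"]], 6.9)
  expect_equal(thr$apd90[["2"]], 7.5)
  expect_equal(thr$triangulation[["1"]], 9.0)
  expect_equal(thr$triangulation[["2"]], 10.2)
  expect_equal(thr$stv[["1"]], 102.6)
  expect_equal(thr$stv[["2"]], 164.3)

  expect_false(classify_change(11.9, "apd30", 1))
  expect_true(classify_change(12.1, "apd30", 1))
  expect_true(classify_change(8.0, "apd90", 2))
  expect_true(classify_change(-8.0, "apd90", 2))   # absolute comparison
  expect_false(classify_change(0, "triangulation", 1))
  expect_error(classify_change(5, "apd30", 3), "pacing rate")
})

test_that("tissue QC enforces the baseline APD90 window and metadata flags", {
  mk <- function(apd90) {
    s <- summarize_ap_train(simulate_ap_train(ap_sim_spec(jitter_sd = 0)))
    s$mean_apd90 <- apd90
    s
  }
  expect_false(qc_tissue(mk(190))$keep)
  expect_match(qc_tissue(mk(190))$reasons, "below 200")
  expect_true(qc_tissue(mk(300))$keep)
  expect_false(qc_tissue(mk(460))$keep)
  expect_match(qc_tissue(mk(460))$reasons, "above 450")
  bad_meta <- qc_tissue(mk(300), metadata = list(perfusion_interrupted = TRUE,
                                                 inadequate_exposure = TRUE))
  expect_false(bad_meta$keep)
  expect_length(bad_meta$reasons, 2)
})

test_that("AP train I/O round trips through CSV plus sidecar", {
  sp <- ap_sim_spec(jitter_sd = 1, n_beats = 5, seed = 3)
  tr <- simulate_ap_train(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ap_train(tr, path)
  back <- read_ap_train(path)
  expect_equal(back$stimulus_times, tr$stimulus_times)
  expect_equal(back$pacing_rate, tr$pacing_rate)
  expect_equal(back$epoch_label, tr$epoch_label)
  expect_lt(max(abs(back$voltage - tr$voltage)), 1e-6)
})

test_that("pacing-rate consistency of stimulus times is enforced", {
  expect_error(ap_train(0.05, rep(-85, 1000), c(0, 400, 1100), 1),
               "pacing_rate")
  expect_error(ap_train(0.05, rep(-85, 1000), c(100, 100), 1), "increasing")
})
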