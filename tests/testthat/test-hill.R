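# Constrained Hill fitting, confidence intervals, ratios.

test_that("Hill relation obeys its closed forms and monotonicity", {
  expect_equal(hill_inhibition(1, 1, 0.7), 0.5)   # c == IC50, any slope
  expect_equal(hill_inhibition(2.5, 2.5, 3), 0.5)
  expect_equal(hill_inhibition(0, 1, 1), 0)
  expect_equal(hill_inhibition(10, 1, 1), 10 / 11)
  cc <- 10^seq(-3, 3, length.out = 50)
  for (nh in c(0.5, 1, 2)) {
    f <- hill_inhibition(cc, ic50 = 0.8, n_h = nh)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f < 1))
  }
  expect_error(hill_inhibition(1, -1, 1), "ic50")
  expect_error(hill_inhibition(1, 1, 0), "n_h")
})

test_that("noiseless points are fit exactly and degenerate inputs error", {
  cc <- c(0.1, 0.3, 1, 3, 10)
  pts <- data.frame(concentration_uM = cc,
                    fraction_inhibited = hill_inhibition(cc, 1, 1))
  fit <- fit_hill(pts)
  expect_lt(abs(fit$ic50 - 1), 1e-6)
  expect_lt(abs(fit$n_h - 1), 1e-6)
  expect_lt(fit$residual_sse, 1e-12)

  expect_error(fit_hill(data.frame(concentration_uM = rep(1, 5),
                                   fraction_inhibited = runif(5))),
               "distinct concentrations")
  expect_error(fit_hill(data.frame(concentration_uM = cc,
                                   fraction_inhibited = rep(0.001, 5))),
               "unidentifiable")
})

test_that("fit is scale-equivariant in concentration", {
  spec <- voltage_clamp_sim_spec(fraction_sd = 0.05, seed = 8)
  pts <- simulate_concentration_response(spec)
  f1 <- fit_hill(pts)
  pts_k <- pts
  pts_k$concentration_uM <- pts$concentration_uM * 1000
  f2 <- fit_hill(pts_k)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-4)
  expect_equal(f2$n_h, f1$n_h, tolerance = 1e-4)
})

test_that("fit agrees with an independent nonlinear least-squares oracle", {
  spec <- voltage_clamp_sim_spec(fraction_sd = 0.05, seed = 21)
  pts <- simulate_concentration_response(spec)
  fit <- fit_hill(pts)
  oracle <- minpack.lm::nlsLM(
    fraction_inhibited ~ 1 / (1 + (10^lg / concentration_uM)^nh),
    data = pts, start = list(lg = 0.5, nh = 1.5)
  )
  co <- coef(oracle)
  expect_equal(fit$ic50, unname(10^co["lg"]), tolerance = 1e-4)
  expect_equal(fit$n_h, unname(co["nh"]), tolerance = 1e-4)
})

test_that("Wald intervals collapse on noiseless data; bootstrap and Wald agree on clean data", {
  cc <- c(0.1, 0.3, 1, 3, 10)
  pts <- data.frame(concentration_uM = rep(cc, each = 3),
                    fraction_inhibited = hill_inhibition(rep(cc, each = 3), 1, 1),
                    cell_id = seq_len(15))
  fw <- hill_ci(fit_hill(pts), method = "wald")
  expect_lt(fw$ic50_ci95[2] - fw$ic50_ci95[1], 1e-3)
  expect_true(fw$ic50_ci95[1] <= fw$ic50 && fw$ic50 <= fw$ic50_ci95[2])

  spec <- voltage_clamp_sim_spec(fraction_sd = 0.05, seed = 13)
  sim <- simulate_concentration_response(spec)
  fb <- hill_ci(fit_hill(sim), method = "bootstrap", n_boot = 400, seed = 2)
  fw2 <- hill_ci(fit_hill(sim), method = "wald")
  # intervals intersect
  expect_lt(max(fb$ic50_ci95[1], fw2$ic50_ci95[1]),
            min(fb$ic50_ci95[2], fw2$ic50_ci95[2]))
  expect_true(fb$ic50_ci95[1] < fb$ic50 && fb$ic50 < fb$ic50_ci95[2])
})

test_that("bootstrap is reproducible under its seed and resamples cells", {
  spec <- voltage_clamp_sim_spec(fraction_sd = 0.05, seed = 4)
  sim <- simulate_concentration_response(spec)
  f1 <- hill_ci(fit_hill(sim), n_boot = 200, seed = 7)
  f2 <- hill_ci(fit_hill(sim), n_boot = 200, seed = 7)
  expect_identical(f1$ic50_ci95, f2$ic50_ci95)
})

test_that("selectivity ratios reproduce the published potency separations", {
  # nifedipine hERG 35 uM vs I_CaL 13.2 nM
  expect_equal(selectivity_ratio(35, 13.2, unit_denominator = "nM")$ratio, 2652)
  expect_lte(abs(selectivity_ratio(35, 13.2, unit_denominator = "nM")$ratio - 2651), 1)
  # nifedipine I_NaL 9.5 uM vs I_CaL 13.2 nM
  expect_equal(selectivity_ratio(9.5, 13.2, unit_denominator = "nM")$ratio, 720)
  # diltiazem, prior data: hERG 6.6 uM vs Ba2+ current 112.1 nM
  expect_equal(selectivity_ratio(6.6, 112.1, unit_denominator = "nM")$ratio, 59)
  # diltiazem, present data: hERG 8.9 uM vs I_CaL 1.3 uM
  expect_equal(selectivity_ratio(8.9, 1.3)$ratio, 7)
  # lidocaine I_NaL, veratridine vs ATX-II protocols
  expect_equal(selectivity_ratio(395.1, 31.7, rounding = "one_decimal")$ratio, 12.5)
  # diltiazem I_CaL, present vs prior
  expect_equal(selectivity_ratio(1.3, 112.1, rounding = "one_decimal",
                                 unit_denominator = "nM")$ratio, 11.6)
  expect_equal(selectivity_ratio(5, 5)$ratio, 1)
  expect_error(selectivity_ratio(-1, 2), "positive")
})

test_that("predicted inhibition at clinical exposure matches the Hill value", {
  fit <- list(ic50 = 1, n_h = 2)
  expect_equal(inhibition_at_exposure(fit, 1), 0.5)
  # dofetilide at free Cmax 1.2 nM: prior IC50 1.3 nM -> ~48% block
  prior <- list(ic50 = as_uM(1.3, "nM"), n_h = 1)
  expect_equal(inhibition_at_exposure(prior, as_uM(1.2, "nM")), 0.48,
               tolerance = 0.01)
  # present IC50 12.3 nM -> ~9% block
  present <- list(ic50 = as_uM(12.3, "nM"), n_h = 1)
  expect_equal(inhibition_at_exposure(present, as_uM(1.2, "nM")), 0.089,
               tolerance = 0.01)
  expect_error(inhibition_at_exposure(fit, 0), "free_cmax")
})
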