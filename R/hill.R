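#' Hill concentration-inhibition relation
#'
#' Variable-slope Hill equation with the minimum and maximum fractional
#' inhibition constrained to 0 and 1:
#' `f(c) = 1 / (1 + (IC50 / c)^nH)`, and `f(0) = 0`.
#'
#' @param concentration drug concentration(s), uM, >= 0.
#' @param ic50 concentration producing 50% inhibition, uM, > 0.
#' @param n_h Hill coefficient, > 0.
#' @return fractional inhibition in `[0, 1)`.
#' @export
#' @examples
#' hill_inhibition(1, ic50 = 1, n_h = 2)     # exactly 0.5
#' hill_inhibition(10, ic50 = 1, n_h = 1)    # 10/11
hill_inhibition <- function(concentration, ic50, n_h) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(n_h <= 0)) stop("n_h must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  out <- 1 / (1 + (ic50 / concentration)^n_h)
  out[concentration == 0] <- 0
  out
}

hill_sse <- function(p, conc, frac) {
  # p = (log10 ic50, log n_h)
  pred <- 1 / (1 + (10^p[1L] / conc)^exp(p[2L]))
  sum((frac - pred)^2)
}

#' Fit the constrained Hill equation to pooled per-cell inhibition data
#'
#' Nonlinear least squares over `(log10 IC50, log nH)` on the pooled
#' per-cell points (points are not averaged per concentration before
#' fitting). A fixed log-spaced multi-start grid spanning the concentration
#' range makes the optimisation deterministic; ties are broken by lowest
#' SSE, then lowest `nH`.
#'
#' @param points data.frame with columns `concentration_uM` (> 0) and
#'   `fraction_inhibited`, plus optional `drug`, `current_type`, `cell_id`.
#' @param n_h_start Hill-coefficient start values for the grid.
#' @param grid_n number of log10 IC50 grid points.
#' @return object of class `hill_fit`: `ic50` (uM), `n_h`, `residual_sse`,
#'   `n_points`, `n_cells_per_concentration`, the data (`points`) and
#'   optimisation diagnostics. CIs are `NA` until [hill_ci()] is applied.
#' @export
fit_hill <- function(points, n_h_start = c(0.5, 1, 2, 4), grid_n = 25L) {
  if (!all(c("concentration_uM", "fraction_inhibited") %in% names(points)))
    stop("points must have columns concentration_uM and fraction_inhibited")
  conc <- points$concentration_uM
  frac <- points$fraction_inhibited
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(unique(conc)) < 2L)
    stop("unidentifiable fit: at least two distinct concentrations are required")
  if (all(abs(frac) < 0.05) || all(frac > 0.95))
    stop("unidentifiable fit: inhibition data are all near 0 or all near 1")
  lg_range <- range(log10(conc))
  grid <- expand.grid(
    lg = seq(lg_range[1L] - 2, lg_range[2L] + 2, length.out = grid_n),
    ln_nh = log(n_h_start)
  )
  sse <- apply(grid, 1L, function(g) hill_sse(c(g[[1L]], g[[2L]]), conc, frac))
  starts <- utils::head(order(sse), 3L)
  fits <- lapply(starts, function(i) {
    stats::optim(
      c(grid$lg[i], grid$ln_nh[i]), hill_sse, conc = conc, frac = frac,
      method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-12)
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  nhs <- vapply(fits, function(f) exp(f$par[2L]), numeric(1))
  best <- order(vals, nhs)[1L]
  fit <- fits[[best]]
  if (fit$convergence != 0)
    stop("Hill fit failed to converge (optim code ", fit$convergence, ")")
  n_per <- table(conc)
  structure(
    list(
      drug = points$drug[1L] %||% NA_character_,
      current_type = points$current_type[1L] %||% NA_character_,
      ic50 = 10^fit$par[1L],
      ic50_ci95 = c(NA_real_, NA_real_),
      n_h = exp(fit$par[2L]),
      n_h_ci95 = c(NA_real_, NA_real_),
      ci_method = NA_character_,
      residual_sse = fit$value,
      n_points = length(conc),
      n_cells_per_concentration = stats::setNames(as.integer(n_per), names(n_per)),
      points = points,
      par = fit$par,
      convergence = fit$convergence
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  ci <- function(v) {
    if (anyNA(v)) "" else sprintf(" (95%% CI %.4g-%.4g)", v[1L], v[2L])
  }
  cat(sprintf(
    "<hill_fit>%s%s IC50 = %.4g uM%s, nH = %.3g%s, SSE = %.4g on %d points\n",
    if (is.na(x$drug)) "" else paste0(" ", x$drug),
    if (is.na(x$current_type)) "" else paste0(" [", x$current_type, "]"),
    x$ic50, ci(x$ic50_ci95), x$n_h, ci(x$n_h_ci95), x$residual_sse, x$n_points
  ))
  invisible(x)
}

# Wald covariance of (log10 ic50, log nH) from the residual Jacobian.
hill_wald_cov <- function(fit) {
  conc <- fit$points$concentration_uM
  frac <- fit$points$fraction_inhibited
  p <- fit$par
  eps <- 1e-6
  pred_at <- function(p) 1 / (1 + (10^p[1L] / conc)^exp(p[2L]))
  J <- vapply(1:2, function(j) {
    dp <- p; dm <- p
    dp[j] <- dp[j] + eps; dm[j] <- dm[j] - eps
    (pred_at(dp) - pred_at(dm)) / (2 * eps)
  }, numeric(length(conc)))
  df <- max(1L, length(conc) - 2L)
  sigma2 <- fit$residual_sse / df
  sigma2 * solve(crossprod(J))
}

#' 95% confidence intervals for a Hill fit
#'
#' Default method is a nonparametric bootstrap that resamples *cells* (the
#' independent experimental units), refitting the model on each resample
#' and taking percentile intervals. The alternative is an asymptotic Wald
#' interval on `(log10 IC50, log nH)` back-transformed to the original
#' scales.
#'
#' @param fit a [fit_hill()] result.
#' @param method `"bootstrap"` or `"wald"`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap (mandatory, documented default 1).
#' @param max_fail_frac maximal tolerated fraction of resamples on which
#'   the refit fails before the bootstrap is declared degenerate.
#' @return the fit with `ic50_ci95`, `n_h_ci95` and `ci_method` filled in.
#' @export
hill_ci <- function(fit, method = c("bootstrap", "wald"), n_boot = 1000L,
                    seed = 1L, max_fail_frac = 0.2) {
  method <- match.arg(method)
  if (method == "wald") {
    V <- hill_wald_cov(fit)
    z <- stats::qnorm(0.975)
    se <- sqrt(pmax(diag(V), 0))
    fit$ic50_ci95 <- 10^(fit$par[1L] + c(-1, 1) * z * se[1L])
    fit$n_h_ci95 <- exp(fit$par[2L] + c(-1, 1) * z * se[2L])
    fit$ci_method <- "wald"
    return(fit)
  }
  pts <- fit$points
  if (is.null(pts$cell_id)) pts$cell_id <- seq_len(nrow(pts))
  cells <- unique(pts$cell_id)
  by_cell <- split(seq_len(nrow(pts)), pts$cell_id)
  boot <- with_local_seed(seed, {
    replicate(n_boot, {
      draw <- sample(cells, length(cells), replace = TRUE)
      idx <- unlist(by_cell[as.character(draw)], use.names = FALSE)
      res <- tryCatch(refit_hill(pts[idx, , drop = FALSE], fit$par),
                      error = function(e) c(NA_real_, NA_real_))
      res
    })
  })
  ok <- !is.na(boot[1L, ])
  if (mean(!ok) > max_fail_frac)
    stop(sprintf("degenerate bootstrap: refit failed on %.0f%% of resamples",
                 100 * mean(!ok)))
  fit$ic50_ci95 <- unname(stats::quantile(boot[1L, ok], c(0.025, 0.975)))
  fit$n_h_ci95 <- unname(stats::quantile(boot[2L, ok], c(0.025, 0.975)))
  fit$ci_method <- "bootstrap"
  fit$n_boot_failed <- sum(!ok)
  fit
}

# Fast single-start refit used inside the bootstrap: starts from the
# full-data solution. Returns c(ic50, n_h).
refit_hill <- function(points, start_par) {
  conc <- points$concentration_uM
  frac <- points$fraction_inhibited
  if (length(unique(conc)) < 2L) stop("degenerate resample")
  fit <- stats::optim(start_par, hill_sse, conc = conc, frac = frac,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  c(10^fit$par[1L], exp(fit$par[2L]))
}

#' Channel-selectivity (potency) ratio
#'
#' Ratio of two IC50s after unit normalisation, with the rounding
#' convention used when quoting the ratio.
#'
#' @param ic50_numerator,ic50_denominator IC50 values (> 0).
#' @param rounding `"nearest_int"`, `"one_decimal"` or `"none"`.
#' @param unit_numerator,unit_denominator concentration units
#'   (see [as_uM()]).
#' @return list of class `selectivity_ratio` with the raw and rounded ratio.
#' @export
#' @examples
#' # nifedipine: hERG 35 uM vs I_CaL 13.2 nM
#' selectivity_ratio(35, 13.2, unit_denominator = "nM")$ratio
selectivity_ratio <- function(ic50_numerator, ic50_denominator,
                              rounding = c("nearest_int", "one_decimal", "none"),
                              unit_numerator = "uM", unit_denominator = "uM") {
  rounding <- match.arg(rounding)
  num <- as_uM(ic50_numerator, unit_numerator)
  den <- as_uM(ic50_denominator, unit_denominator)
  if (num <= 0 || den <= 0) stop("IC50s must be positive")
  raw <- num / den
  ratio <- switch(rounding,
    nearest_int = round(raw),
    one_decimal = round(raw, 1L),
    none = raw
  )
  structure(list(ratio = ratio, raw_ratio = raw, rounding = rounding),
            class = "selectivity_ratio")
}

#' Predicted inhibition at a clinical exposure
#'
#' Evaluates the fitted Hill model at the free maximal plasma concentration
#' (free Cmax).
#'
#' @param fit a [fit_hill()] result (or any list with `ic50`, `n_h`).
#' @param free_cmax free clinical Cmax in uM (> 0).
#' @return predicted fractional inhibition.
#' @export
inhibition_at_exposure <- function(fit, free_cmax) {
  if (free_cmax <= 0) stop("free_cmax must be > 0")
  hill_inhibition(free_cmax, fit$ic50, fit$n_h)
}
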