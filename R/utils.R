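#' Convert a concentration to micromolar
#'
#' All concentrations inside the package are stored in uM; inputs may be
#' declared in nM, uM, mM or M.
#'
#' @param value numeric concentration(s).
#' @param unit one of `"nM"`, `"uM"`, `"mM"`, `"M"` (`"µM"` is accepted as a
#'   synonym for `"uM"`).
#' @return numeric, concentration in uM.
#' @export
#' @examples
#' as_uM(13.2, "nM")
as_uM <- function(value, unit = "uM") {
  unit <- gsub("µ", "u", unit)
  factor <- switch(unit,
    nM = 1e-3,
    uM = 1,
    mM = 1e3,
    M  = 1e6,
    stop("unknown concentration unit: ", unit)
  )
  value * factor
}

# Centered moving average; k is forced odd so the filter does not shift the
# trace. Edges fall back to the raw samples.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# First time at which the piecewise-linear trace v(t) crosses `level` in the
# given direction ("down" = from above to at/below), searching indices
# idx_start..idx_end. Returns NA_real_ when the level is never crossed.
first_crossing_time <- function(t, v, level, direction = c("down", "up"),
                                idx_start = 1L, idx_end = length(v)) {
  direction <- match.arg(direction)
  idx <- idx_start:(idx_end - 1L)
  if (direction == "down") {
    hit <- which(v[idx] > level & v[idx + 1L] <= level)
  } else {
    hit <- which(v[idx] < level & v[idx + 1L] >= level)
  }
  if (length(hit) == 0L) return(NA_real_)
  i <- idx[hit[1L]]
  # linear interpolation between samples i and i+1
  frac <- (level - v[i]) / (v[i + 1L] - v[i])
  t[i] + frac * (t[i + 1L] - t[i])
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
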