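# Internal numerical helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Trapezoidal area under a sampled curve
#'
#' @param x abscissa, strictly increasing.
#' @param y ordinate, same length as `x`.
#' @return Scalar area in `units(x) * units(y)`.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Trapezoidal area over a sub-interval, with interpolated endpoints
#'
#' Integrates the piecewise-linear interpolant of `(x, y)` over
#' `[lo, hi]`. Window endpoints that fall between samples are obtained by
#' linear interpolation, so the result is exact for the interpolant.
#'
#' @param x,y sampled curve, `x` strictly increasing.
#' @param lo,hi integration bounds, must lie within `range(x)`.
#' @keywords internal
trapz_window <- function(x, y, lo, hi) {
  stopifnot(hi >= lo)
  if (lo < x[1L] || hi > x[length(x)]) {
    stop("integration window [", lo, ", ", hi, "] outside curve range [",
         x[1L], ", ", x[length(x)], "]")
  }
  if (hi == lo) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y,
          y[inside],
          stats::approx(x, y, xout = hi)$y)
  trapz(xs, ys)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated-normal draws by rejection; the support is wide relative to the
# sd used here so rejection is cheap and exact.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    cand <- stats::rnorm(length(todo), mean[todo], sd[todo])
    ok <- cand >= lo & cand <= hi
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}
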