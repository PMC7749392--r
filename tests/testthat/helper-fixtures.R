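# Shared fixtures and independent oracles used across the suite.

# A well-behaved Chesler-Cram parameter set in the generator's range.
demo_cce <- function(y0 = 2, xc1 = 300, A = 22, w = 2500, k2 = 0.02,
                     xc2 = 180, B = 0.35, k3 = 0.03, xc3 = 330) {
  cce_params(y0 = y0, xc1 = xc1, A = A, w = w, k2 = k2, xc2 = xc2,
             B = B, k3 = k3, xc3 = xc3)
}

# Independent transcription of the Chesler-Cram peak function, written
# term by term from the printed formula and kept separate from the
# package's vectorised implementation.
cce_oracle <- function(p, x) {
  vapply(x, function(xx) {
    gauss <- exp(-((xx - p[["xc1"]])^2) / (2 * p[["w"]]))
    sig <- 1 - 0.5 * (1 - tanh(p[["k2"]] * (xx - p[["xc2"]])))
    dec <- exp(-0.5 * p[["k3"]] * (abs(xx - p[["xc3"]]) + (xx - p[["xc3"]])))
    p[["y0"]] + p[["A"]] * (gauss + p[["B"]] * sig * dec)
  }, numeric(1L))
}

# Riemann mid-point sum on a very fine grid of the piecewise-linear
# interpolant: reference for trapezoidal window areas.
riemann_oracle <- function(x, y, lo, hi, n = 200000L) {
  g <- seq(lo, hi, length.out = n)
  mid <- (g[-1L] + g[-n]) / 2
  sum(stats::approx(x, y, xout = mid)$y * diff(g))
}

# Brute-force Spearman: classic tie-free formula 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_oracle_tiefree <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small panel of three well-separated point triples in the volume plane.
separated_triples <- function() {
  tibble::tibble(
    sample_id = sprintf("T%d", 1:9),
    volume_A_ml_per_g = c(3.2, 3.25, 3.3, 2.4, 2.45, 2.5, 1.7, 1.75, 1.8),
    volume_B_ml_per_g = c(2.7, 2.75, 2.8, 1.5, 1.55, 1.6, 1.15, 1.2, 1.25),
    truth = rep(c("good", "medium", "poor"), each = 3)
  )
}
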