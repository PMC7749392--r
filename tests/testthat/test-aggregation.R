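make_curve <- function(time, torque) aggregation_curve(time, torque)

test_that("BEM and PMT are the torque maximum and its time", {
  # spike of 30 BU at t = 250 s within a 10-point trace
  t <- c(0, 50, 100, 150, 200, 250, 300, 350, 400, 450)
  y <- c(0, 2, 5, 12, 20, 30, 18, 10, 6, 4)
  bp <- extract_bem_pmt(make_curve(t, y))
  expect_equal(bp$BEM, 30)
  expect_equal(bp$PMT, 250)
  expect_false(bp$constant)
})

test_that("PMT ties resolve to the earliest time", {
  t <- seq(0, 90, by = 10)
  y <- c(0, 5, 30, 30, 30, 10, 5, 4, 3, 2)
  expect_equal(extract_bem_pmt(make_curve(t, y))$PMT, 20)
})

test_that("constant traces are flagged and keep the first time point", {
  t <- seq(0, 90, by = 10)
  expect_warning(bp <- extract_bem_pmt(make_curve(t, rep(7, 10))), "constant")
  expect_equal(bp$BEM, 7)
  expect_equal(bp$PMT, 0)
  expect_true(bp$constant)
})

test_that("BEM/PMT are invariant to appending lower-torque points", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  bp0 <- extract_bem_pmt(cv)
  ext <- aggregation_curve(c(cv$time, 601:650),
                           c(cv$torque, rep(bp0$BEM - 1, 50)))
  bp1 <- extract_bem_pmt(ext)
  expect_equal(bp1$BEM, bp0$BEM)
  expect_equal(bp1$PMT, bp0$PMT)
})

test_that("peak areas on constant torque match the rectangle values", {
  t <- seq(0, 600, by = 5)
  cv <- make_curve(t, rep(4, length(t)))
  ar <- compute_peak_areas(cv, pmt = 300)
  expect_equal(ar$peak30, 30 * 4)
  expect_equal(ar$peak180, 135 * 4)
  expect_equal(ar$ratio30_180, 2 / 9)
})

test_that("at PMT = 195 s the two windows coincide and the ratio is 1", {
  t <- seq(0, 600, by = 5)
  cv <- make_curve(t, rep(3, length(t)))
  ar <- compute_peak_areas(cv, pmt = 195)
  expect_equal(ar$peak30, ar$peak180)
  expect_equal(ar$ratio30_180, 1)
})

test_that("early PMT clamps the lower window bound and flags ratios above 1", {
  t <- seq(0, 600, by = 5)
  cv <- make_curve(t, rep(2, length(t)))
  expect_warning(ar <- compute_peak_areas(cv, pmt = 10), "clamped")
  expect_true("peak30_window_clamped" %in% ar$flags)
  expect_true(is.na(ar$ratio30_180))  # peak180 window degenerates to nothing
  # PMT in (165, 195): peak180 window lies strictly inside peak30
  expect_warning(ar2 <- compute_peak_areas(cv, pmt = 175), "inside")
  expect_equal(ar2$peak30, 60)
  expect_equal(ar2$peak180, 20)
  expect_gt(ar2$ratio30_180, 1)
  expect_true("ratio_above_one" %in% ar2$flags)
})

test_that("window areas agree with a fine-grid Riemann oracle", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  bp <- extract_bem_pmt(cv)
  ar <- compute_peak_areas(cv, bp$PMT)
  o30 <- riemann_oracle(cv$time, cv$torque, bp$PMT - 15, bp$PMT + 15)
  o180 <- riemann_oracle(cv$time, cv$torque, 180, bp$PMT + 15)
  expect_lte(abs(ar$peak30 - o30) / o30, 0.001)
  expect_lte(abs(ar$peak180 - o180) / o180, 0.001)
})

test_that("ratio lies in (0, 1] whenever PMT >= 195 s", {
  panel <- generate_panel(panel_config(n_samples = 30, rng_seed = 13))
  for (id in panel$records$sample_id) {
    cv <- panel$aggregation_curves[[id]]
    bp <- extract_bem_pmt(cv)
    if (bp$PMT >= 195) {
      ar <- compute_peak_areas(cv, bp$PMT)
      expect_gt(ar$ratio30_180, 0)
      expect_lte(ar$ratio30_180, 1)
      expect_lte(ar$peak30, ar$peak180)
    }
  }
})

test_that("the peak function matches an independent transcription", {
  p <- demo_cce()
  x <- seq(-50, 650, by = 0.7)
  expect_equal(cce_eval(p, x), cce_oracle(unclass(p), x), tolerance = 1e-12)
})

test_that("peak function limits behave as the formula implies", {
  p <- demo_cce(B = 0)
  expect_equal(cce_eval(p, 300), 2 + 22)        # apex: y0 + A at x = xc1
  p2 <- demo_cce()
  expect_equal(cce_eval(p2, -1e6), 2, tolerance = 1e-9)  # both terms vanish
})

test_that("cce_eval validates the width and supports both conventions", {
  p <- unclass(demo_cce())
  p["w"] <- -1
  expect_error(cce_eval(structure(p, class = "cce_params"), 0), "w")
  p3 <- demo_cce(w = 50, B = 0)
  # squared convention: denominator 2*w^2, so a wider Gaussian
  at <- 300 + 50
  lin <- cce_eval(p3, at)                        # exp(-2500/100) tiny
  sq <- cce_eval(p3, at, gaussian_convention = "squared")  # exp(-0.5)
  expect_lt(lin - 2, 1e-9)
  expect_equal(sq - 2, 22 * exp(-0.5), tolerance = 1e-12)
})

test_that("cce_params validates finiteness, amplitude and width", {
  expect_error(cce_params(0, 1, -2, 1, 1, 1, 1, 1, 1), "non-negative")
  expect_error(cce_params(0, 1, 2, 0, 1, 1, 1, 1, 1), "positive")
  expect_error(cce_params(NA, 1, 2, 1, 1, 1, 1, 1, 1), "finite")
})

test_that("noise-free fits recover the generating parameters", {
  panel <- generate_panel(panel_config(n_samples = 3, rng_seed = 3,
                                       aggregation_noise_sd = 0))
  for (id in panel$records$sample_id) {
    fit <- fit_cce(panel$aggregation_curves[[id]])
    tr <- unlist(panel$truth[panel$truth$sample_id == id,
                             c("y0", "xc1", "A", "w", "k2", "xc2", "B",
                               "k3", "xc3")])
    rel <- abs(unclass(fit$params)[names(tr)] - tr) / abs(tr)
    expect_lt(max(rel), 1e-3)
    expect_gt(fit$r_squared, 1 - 1e-9)
    expect_true(fit$converged)
  }
})

test_that("the fit never does worse than its feature-based start", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 1.0, seed = 21)
  fit <- fit_cce(cv)
  # rebuild one start of the published grid from the same features
  bp <- extract_bem_pmt(cv)
  y0i <- stats::median(cv$torque[cv$time <= 60])
  half <- y0i + (bp$BEM - y0i) / 2
  fw <- diff(range(cv$time[cv$torque >= half]))
  start <- cce_params(y0 = y0i, xc1 = bp$PMT, A = bp$BEM - y0i,
                      w = fw^2 / (2 * log(4)), k2 = 0.01, xc2 = 0.8 * bp$PMT,
                      B = 0.1, k3 = 0.02, xc3 = bp$PMT)
  sse_start <- sum((cv$torque - cce_eval(start, cv$time))^2)
  expect_lte(fit$sse, sse_start)
})

test_that("fits are scale-consistent in amplitude", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  sc <- aggregation_curve(cv$time, cv$torque * 3)
  f1 <- fit_cce(cv)
  f3 <- fit_cce(sc)
  expect_equal(f3$params[["y0"]], 3 * f1$params[["y0"]], tolerance = 1e-3)
  expect_equal(f3$params[["A"]], 3 * f1$params[["A"]], tolerance = 1e-3)
  expect_equal(f3$params[["xc1"]], f1$params[["xc1"]], tolerance = 1e-3)
})

test_that("fit_cce refuses short traces", {
  t <- seq(0, 180, by = 10)
  expect_error(fit_cce(aggregation_curve(t, seq_along(t))), "20 points")
})

test_that("the full aggregation feature row carries all fields", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  row <- extract_aggregation_features(cv)
  expect_true(all(c("BEM", "PMT", "peak30", "peak180", "peak30_peak180",
                    "y0", "xc1", "A", "w", "k2", "xc2", "B", "k3", "xc3",
                    "r_squared") %in% names(row)))
  row2 <- extract_aggregation_features(cv, fit_model = FALSE)
  expect_false("xc1" %in% names(row2))
})

test_that("curve validation rejects malformed traces", {
  expect_error(aggregation_curve(c(0, 1, 2), c(1, 2, 3)), "10 points")
  t <- seq(0, 90, 10)
  expect_error(aggregation_curve(rev(t), rep(1, 10)), "increasing")
  expect_error(aggregation_curve(t, c(rep(1, 9), -1)), "non-negative")
  expect_error(aggregation_curve(t, c(rep(1, 9), NA)), "NA")
})
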