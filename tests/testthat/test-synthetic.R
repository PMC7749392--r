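test_that("panel volumes stay within the published recipe ranges", {
  panel <- generate_panel(panel_config(n_samples = 46, rng_seed = 1))
  r <- panel$records
  expect_equal(nrow(r), 46L)
  expect_true(all(r$volume_A_ml_per_g >= 1.6 & r$volume_A_ml_per_g <= 3.5))
  expect_true(all(r$volume_B_ml_per_g >= 1.1 & r$volume_B_ml_per_g <= 3.0))
})

test_that("recipe B is a monotone transform of recipe A in the noise-free limit", {
  panel <- generate_panel(panel_config(n_samples = 300, volume_noise_sd = 0,
                                       rng_seed = 2))
  sp <- spearman_cor(panel$records$volume_A_ml_per_g,
                     panel$records$volume_B_ml_per_g)
  expect_equal(sp$r, 1.0)
})

test_that("between-recipe rank correlation sits in the calibrated band", {
  panel <- generate_panel(panel_config(n_samples = 300, rng_seed = 7))
  sp <- spearman_cor(panel$records$volume_A_ml_per_g,
                     panel$records$volume_B_ml_per_g)
  expect_gte(sp$r, 0.8)
  expect_lte(sp$r, 1.0)
})

test_that("fixed seed gives a bit-identical panel", {
  a <- generate_panel(panel_config(n_samples = 15, rng_seed = 9))
  b <- generate_panel(panel_config(n_samples = 15, rng_seed = 9))
  expect_identical(a, b)
})

test_that("class-conditional volume means are strictly ordered", {
  panel <- generate_panel(panel_config(n_samples = 120, rng_seed = 4))
  m <- tapply(panel$records$volume_A_ml_per_g, panel$records$true_class, mean)
  expect_true(m[["good"]] > m[["medium"]])
  expect_true(m[["medium"]] > m[["poor"]])
})

test_that("proportions that empty a class raise an error naming it", {
  expect_error(generate_panel(panel_config(n_samples = 5,
                                           class_proportions = c(0.9, 0.08, 0.02))),
               "poor")
})

test_that("panel config validates its invariants", {
  expect_error(panel_config(n_samples = 2), "n_samples")
  expect_error(panel_config(class_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(panel_config(volume_noise_sd = -1))
})

test_that("noise-free aggregation curve equals the model pointwise", {
  p <- demo_cce()
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  expect_equal(cv$torque, cce_eval(p, cv$time))
})

test_that("pure-Gaussian curve peaks at its centre", {
  p <- demo_cce(xc1 = 250, A = 25, y0 = 5, B = 0)
  cv <- generate_aggregation_curve(p, noise_sd = 0)
  expect_equal(cv$time[which.max(cv$torque)], 250)
})

test_that("aggregation curve is byte-identical under a fixed seed", {
  p <- demo_cce()
  a <- generate_aggregation_curve(p, noise_sd = 0.5, seed = 123)
  b <- generate_aggregation_curve(p, noise_sd = 0.5, seed = 123)
  expect_identical(a, b)
})

test_that("aggregation generator rejects bad inputs", {
  p <- unclass(demo_cce())
  p["A"] <- Inf
  expect_error(generate_aggregation_curve(structure(p, class = "cce_params")),
               "finite")
  expect_error(generate_aggregation_curve(demo_cce(), duration = 300))
})

test_that("noise-free extension curve peaks exactly at (e_rmax, rmax)", {
  cv <- generate_extension_curve(rmax = 1.0, e_rmax = 50, e_max = 70,
                                 noise_sd = 0)
  expect_equal(max(cv$force), 1.0)
  expect_equal(cv$distance[which.max(cv$force)], 50)
})

test_that("extension features round-trip the generator targets", {
  cases <- list(c(1.0, 50, 70), c(0.8, 38.3, 47.1), c(1.15, 66.5, 78.1))
  for (cs in cases) {
    cv <- generate_extension_curve(rmax = cs[1L], e_rmax = cs[2L],
                                   e_max = cs[3L], noise_sd = 0,
                                   interval = 0.1)
    ft <- extract_extension_features(cv)
    expect_equal(ft$R_max, cs[1L], tolerance = 1e-6)
    expect_lte(abs(ft$E_Rmax - cs[2L]), 0.1)
    expect_lte(abs(ft$E_max - cs[3L]), 0.1)
  }
})

test_that("extension generator rejects inverted geometry", {
  expect_error(generate_extension_curve(1, e_rmax = 70, e_max = 50), "e_rmax")
  expect_error(generate_extension_curve(-1, e_rmax = 40, e_max = 50), "rmax")
})

test_that("chromatogram pair round-trips its composition", {
  comp <- c(gliadin_hmw = 12, gliadin_mmw = 8, gliadin_lmw = 40,
            glutenin_hmw = 2, glutenin_mmw = 8, glutenin_lmw = 30)
  ch <- generate_chromatogram(comp, noise_sd = 0, seed = 1)
  gl <- integrate_windows(ch$gliadin, baseline_correct = FALSE)
  gu <- integrate_windows(ch$glutenin, baseline_correct = FALSE)
  got <- compose_composition(gl, gu)
  expect_lte(abs(got$gliadin_total - 60), 2)
  # GLIA/GLUT 1.5 target recovered within 0.1
  expect_lte(abs(got$glia_glut_ratio - 1.5), 0.1)
})

test_that("all mass in one window integrates to 100% there", {
  comp <- c(gliadin_hmw = 100, gliadin_mmw = 0, gliadin_lmw = 0,
            glutenin_hmw = 0, glutenin_mmw = 0, glutenin_lmw = 0)
  ch <- generate_chromatogram(comp, noise_sd = 0, seed = 1)
  gl <- integrate_windows(ch$gliadin, baseline_correct = FALSE)
  gu <- integrate_windows(ch$glutenin, baseline_correct = FALSE)
  # the glutenin trace is empty, so the ratio is flagged as undefined
  expect_warning(got <- compose_composition(gl, gu), "undefined")
  expect_gte(got$gliadin_hmw, 99.5)
})

test_that("chromatogram generator validates fractions", {
  bad <- c(gliadin_hmw = 120, gliadin_mmw = -20, gliadin_lmw = 0,
           glutenin_hmw = 0, glutenin_mmw = 0, glutenin_lmw = 0)
  expect_error(generate_chromatogram(bad), "\\[0, 100\\]")
  expect_error(generate_chromatogram(c(gliadin_hmw = 50, gliadin_mmw = 10,
                                       gliadin_lmw = 10, glutenin_hmw = 10,
                                       glutenin_mmw = 10, glutenin_lmw = 5)),
               "sum to 100")
})

test_that("panel GLIA/GLUT ratios stay in the published range", {
  panel <- generate_panel(panel_config(n_samples = 80, rng_seed = 6))
  expect_true(all(panel$truth$glia_glut_ratio >= 1.2 &
                    panel$truth$glia_glut_ratio <= 2.8))
})

test_that("noise-free curves reproduce generating feature values", {
  panel <- generate_panel(panel_config(
    n_samples = 6, rng_seed = 8, aggregation_noise_sd = 0,
    extension_noise_sd = 0, chromatogram_noise_sd = 0))
  for (id in panel$records$sample_id) {
    tr <- panel$truth[panel$truth$sample_id == id, ]
    bp <- extract_bem_pmt(panel$aggregation_curves[[id]])
    # the curve's true apex: fine-grid argmax of the generating model
    pars <- do.call(cce_params, as.list(unlist(
      tr[, c("y0", "xc1", "A", "w", "k2", "xc2", "B", "k3", "xc3")])))
    fine <- seq(0, 600, by = 0.1)
    apex <- fine[which.max(cce_eval(pars, fine))]
    expect_lte(abs(bp$PMT - apex), 1)  # within one sampling interval
    ft <- extract_extension_features(panel$extension_curves[[id]])
    expect_lte(abs(ft$E_Rmax - tr$E_Rmax), 0.1)
    expect_lte(abs(ft$E_max - tr$E_max), 0.1)
    expect_lte(abs(ft$R_max - tr$R_max), 1e-6)
  }
})

test_that("large-panel feature correlations match the published signs", {
  panel <- generate_panel(panel_config(n_samples = 250, rng_seed = 11))
  feats <- extract_panel_features(panel, include_cce = FALSE)
  truth_cce <- panel$truth[, c("sample_id", "y0", "xc1", "A", "w", "k2",
                               "xc2", "B", "k3", "xc3")]
  all_f <- merge(feats[, c("sample_id", "BEM", "PMT", "peak180",
                           "peak30_peak180", "E_Rmax", "A_Rmax", "E_max",
                           "A_max")],
                 truth_cce, by = "sample_id")
  ct <- correlation_table(all_f, panel$records)
  expected_sign <- c(BEM = 1, PMT = -1, peak180 = -1, peak30_peak180 = 1,
                     xc1 = -1, w = -1, xc2 = 1, xc3 = -1,
                     E_Rmax = 1, A_Rmax = 1, E_max = 1, A_max = 1)
  got <- ct[ct$parameter %in% names(expected_sign), ]
  expect_true(all(sign(got$r_A) == expected_sign[got$parameter]))
  expect_true(all(sign(got$r_B) == expected_sign[got$parameter]))
  expect_true(all(got$significant_both))
})

test_that("write_panel exports the documented CSV layout", {
  dir <- withr::local_tempdir()
  panel <- generate_panel(panel_config(n_samples = 3, rng_seed = 2))
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "samples.csv")))
  expect_true(file.exists(file.path(dir, "S01_aggregation.csv")))
  expect_true(file.exists(file.path(dir, "S02_extension.csv")))
  expect_true(file.exists(file.path(dir, "S03_gliadin.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  cv <- utils::read.csv(file.path(dir, "S01_aggregation.csv"))
  expect_named(cv, c("time_s", "torque_BU"))
})
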