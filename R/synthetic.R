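#' Configuration for a synthetic vital-gluten sample panel
#'
#' Defines the generating conditions of a synthetic panel: panel size,
#' quality-class mixture, measurement-noise levels and sampling grids.
#' Defaults emulate the 46-sample reference panel: class proportions
#' 23/15/8, specific volumes spanning 1.6-3.5 ml/g (recipe A) and
#' 1.1-3.0 ml/g (recipe B), and a between-recipe volume rank correlation
#' near 0.89.
#'
#' All modalities derive from one per-sample latent quality scalar `q` in
#' (0, 1): class-conditional truncated Gaussians (centres
#' `class_centers`, common sd `class_sd`) generate `q`, and every feature
#' target is a direction-consistent affine map of a jittered copy of `q`
#' (`trait_sd` controls the jitter), which guarantees the cross-modal
#' correlation structure the downstream analysis assumes.
#'
#' @param n_samples panel size (>= 3).
#' @param class_proportions three fractions (good, medium, poor) in (0,1)
#'   summing to 1.
#' @param volume_noise_sd sd of the recipe-B volume noise, ml/g. The
#'   default 0.2 puts the expected Spearman correlation between recipes
#'   near the observed 0.89.
#' @param aggregation_noise_sd torque noise sd, BU.
#' @param extension_noise_sd force noise sd, N (well below the 0.020 N
#'   break sensitivity so spurious rupture detections are negligible).
#' @param chromatogram_noise_sd baseline noise sd of the HPLC traces,
#'   absorbance units.
#' @param rng_seed integer seed; fixed seed gives a bit-identical panel.
#' @param aggregation_interval torque sampling interval, s.
#' @param aggregation_duration length of the aggregation trace, s (>= 600).
#' @param extension_interval distance sampling interval, mm.
#' @param class_centers latent-quality centres of the three classes,
#'   descending.
#' @param class_sd common within-class sd of the latent quality scalar.
#' @param trait_sd sd of the per-feature jitter added to `q` before the
#'   affine maps; larger values weaken feature-volume correlations.
#' @return Object of class `panel_config` (a validated list).
#' @export
panel_config <- function(n_samples = 46L,
                         class_proportions = c(good = 23, medium = 15, poor = 8) / 46,
                         volume_noise_sd = 0.2,
                         aggregation_noise_sd = 0.5,
                         extension_noise_sd = 0.002,
                         chromatogram_noise_sd = 0.02,
                         rng_seed = 1L,
                         aggregation_interval = 1,
                         aggregation_duration = 600,
                         extension_interval = 0.1,
                         class_centers = c(good = 0.77, medium = 0.54, poor = 0.22),
                         class_sd = 0.10,
                         trait_sd = 0.12) {
  stopifnot(n_samples >= 3L, length(class_proportions) == 3L)
  if (any(class_proportions <= 0) || any(class_proportions >= 1)) {
    stop("class proportions must lie in (0, 1)")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1")
  }
  stopifnot(volume_noise_sd >= 0, aggregation_noise_sd >= 0,
            extension_noise_sd >= 0, chromatogram_noise_sd >= 0,
            aggregation_interval > 0, extension_interval > 0,
            aggregation_duration >= 600, class_sd >= 0, trait_sd >= 0,
            all(diff(class_centers) < 0))
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = stats::setNames(class_proportions,
                                                     c("good", "medium", "poor")),
                 volume_noise_sd = volume_noise_sd,
                 aggregation_noise_sd = aggregation_noise_sd,
                 extension_noise_sd = extension_noise_sd,
                 chromatogram_noise_sd = chromatogram_noise_sd,
                 rng_seed = as.integer(rng_seed),
                 aggregation_interval = aggregation_interval,
                 aggregation_duration = aggregation_duration,
                 extension_interval = extension_interval,
                 class_centers = class_centers,
                 class_sd = class_sd,
                 trait_sd = trait_sd),
            class = "panel_config")
}

# largest-remainder apportionment of n samples to the three classes
class_counts <- function(n, proportions) {
  base <- floor(proportions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- proportions * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  counts <- stats::setNames(as.integer(base), names(proportions))
  empty <- names(counts)[counts == 0L]
  if (length(empty) > 0L) {
    stop("class proportions yield an empty class: ",
         paste(empty, collapse = ", "))
  }
  counts
}

#' Generate a synthetic gluten aggregation curve
#'
#' Evaluates the Chesler-Cram peak function on a regular time grid
#' starting at 0 (onset of the high-speed mixing phase) and adds i.i.d.
#' Gaussian torque noise, clipped at zero.
#'
#' @param cce a [cce_params()] object.
#' @param noise_sd torque noise sd, BU.
#' @param interval sampling interval, s.
#' @param duration trace length, s (>= 600).
#' @param seed optional integer; `NULL` draws from the ambient RNG stream.
#' @return An [aggregation_curve()].
#' @export
generate_aggregation_curve <- function(cce, noise_sd = 0.5, interval = 1,
                                       duration = 600, seed = NULL) {
  if (!all(is.finite(unclass(cce)))) stop("CCE parameters must be finite")
  stopifnot(duration >= 600, interval > 0, noise_sd >= 0)
  with_seed(seed, {
    time <- seq(0, duration, by = interval)
    clean <- cce_eval(cce, time)
    torque <- clean + if (noise_sd > 0) stats::rnorm(length(time), 0, noise_sd) else 0
    aggregation_curve(time, pmax(torque, 0))
  })
}

#' Generate a synthetic microscale extension curve
#'
#' Smooth unimodal force profile `f(d) = rmax * (d/e_rmax) *
#' exp(1 - d/e_rmax)` peaking at `(e_rmax, rmax)`, truncated to zero force
#' beyond the rupture distance `e_max`, plus Gaussian force noise clipped
#' at zero. The drop at `e_max` far exceeds any realistic break
#' sensitivity, so rupture detection recovers `e_max` to within one
#' sampling interval.
#'
#' @param rmax peak force, N (> 0).
#' @param e_rmax distance of the peak, mm (0 < e_rmax < e_max).
#' @param e_max rupture distance, mm.
#' @param noise_sd force noise sd, N.
#' @param interval sampling interval, mm.
#' @param tail_mm distance recorded beyond the rupture, mm.
#' @param seed optional integer; `NULL` draws from the ambient RNG stream.
#' @return An [extension_curve()].
#' @export
generate_extension_curve <- function(rmax, e_rmax, e_max, noise_sd = 0.002,
                                     interval = 0.1, tail_mm = 10,
                                     seed = NULL) {
  if (!(e_rmax > 0 && e_rmax < e_max)) stop("need 0 < e_rmax < e_max")
  if (rmax <= 0) stop("rmax must be positive")
  stopifnot(interval > 0, interval <= 1, noise_sd >= 0)
  with_seed(seed, {
    d <- seq(0, e_max + tail_mm, by = interval)
    f <- rmax * (d / e_rmax) * exp(1 - d / e_rmax)
    f[d > e_max] <- 0
    if (noise_sd > 0) f <- f + stats::rnorm(length(d), 0, noise_sd)
    extension_curve(d, pmax(f, 0))
  })
}

#' Generate a synthetic pair of GP-HPLC chromatograms
#'
#' One gliadin and one glutenin trace, each a sum of Gaussian peaks
#' centred inside the molecular-weight retention windows of
#' [retention_windows()], scaled so that window integration with the
#' identity calibration recovers the target masses. Peak widths are chosen
#' so that far less than 1% of each peak's mass leaks out of its window.
#'
#' @param composition named numeric vector of the six target fractions
#'   (`gliadin_hmw`, `gliadin_mmw`, `gliadin_lmw`, `glutenin_hmw`,
#'   `glutenin_mmw`, `glutenin_lmw`), percentages summing to 100.
#' @param total_mass_ug total protein mass represented by the pair, ug.
#' @param noise_sd baseline noise sd, absorbance units.
#' @param interval retention sampling interval, min.
#' @param seed optional integer; `NULL` draws from the ambient RNG stream.
#' @return List with elements `gliadin` and `glutenin`, each a
#'   [chromatogram()].
#' @export
generate_chromatogram <- function(composition, total_mass_ug = 30,
                                  noise_sd = 0.02, interval = 0.01,
                                  seed = NULL) {
  needed <- c("gliadin_hmw", "gliadin_mmw", "gliadin_lmw",
              "glutenin_hmw", "glutenin_mmw", "glutenin_lmw")
  comp <- unlist(composition)[needed]
  if (anyNA(comp)) stop("composition must name all six fractions")
  if (any(comp < 0 | comp > 100)) stop("fractions must lie in [0, 100]")
  if (abs(sum(comp) - 100) > 1e-6) stop("fractions must sum to 100")
  centres <- list(gliadin = c(7.05, 8.60, 10.80), glutenin = c(6.70, 8.00, 10.50))
  sds <- list(gliadin = c(0.25, 0.12, 0.45), glutenin = c(0.17, 0.14, 0.45))
  with_seed(seed, {
    rt <- seq(5.5, 13.5, by = interval)
    out <- lapply(c(gliadin = "gliadin", glutenin = "glutenin"), function(ex) {
      masses <- total_mass_ug * comp[paste0(ex, c("_hmw", "_mmw", "_lmw"))] / 100
      sig <- numeric(length(rt))
      for (j in 1:3) {
        sig <- sig + masses[j] * stats::dnorm(rt, centres[[ex]][j], sds[[ex]][j])
      }
      if (noise_sd > 0) sig <- sig + stats::rnorm(length(rt), 0, noise_sd)
      chromatogram(rt, pmax(sig, 0), extract = ex)
    })
    out
  })
}

#' Generate a full synthetic sample panel
#'
#' Draws latent quality scalars per class, maps them to specific volumes
#' and to the generating parameters of all three measurement modalities,
#' and synthesises one aggregation curve, one extension curve and one
#' chromatogram pair per sample. Recipe-B volumes are a monotone affine
#' transform of recipe-A volumes plus noise. Feature targets follow the
#' published correlation directions: good samples have low PMT, high BEM,
#' narrow peaks and long extensibility; poor samples the reverse.
#'
#' @param config a [panel_config()].
#' @return Object of class `gluten_panel`: list with `records` (tibble:
#'   `sample_id`, `volume_A_ml_per_g`, `volume_B_ml_per_g`, `true_class`),
#'   `aggregation_curves`, `extension_curves`, `chromatograms` (named
#'   lists, one element per sample), `truth` (tibble of all generating
#'   parameters) and `config`.
#' @examples
#' panel <- generate_panel(panel_config(n_samples = 12, rng_seed = 7))
#' panel$records
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_samples
  counts <- class_counts(n, config$class_proportions)
  with_seed(config$rng_seed, {
    classes <- sample(rep(names(counts), counts))
    q <- rnorm_trunc(n, config$class_centers[classes], config$class_sd,
                     0.02, 0.98)

    vol_A <- 1.6 + 1.9 * q
    vol_B <- clamp(vol_A - 0.5 + stats::rnorm(n, 0, config$volume_noise_sd),
                   1.1, 3.0)

    trait <- function() clamp(q + stats::rnorm(n, 0, config$trait_sd), 0.01, 0.99)

    # aggregation generating parameters (correlation directions as
    # published; target spans leave margin inside the published observed
    # ranges for noise-driven inflation of the extracted extrema)
    pmt_t <- 465 - 245 * trait()          # s, decreasing in quality
    bem_t <- 23.8 + 8.0 * trait()         # BU, increasing
    w_t <- 3900 - 2800 * trait()          # s^2, decreasing (sharper peaks)
    xc2_t <- 90 + 140 * trait()           # s, increasing
    y0_t <- clamp(1.0 + stats::rnorm(n, 0, 0.12), 0.7, 1.3)
    B_t <- clamp(0.20 + stats::rnorm(n, 0, 0.02), 0.14, 0.26)
    k2_t <- clamp(0.022 + stats::rnorm(n, 0, 0.003), 0.012, 0.032)
    k3_t <- clamp(0.030 + stats::rnorm(n, 0, 0.004), 0.018, 0.042)
    xc3_t <- pmt_t + 30
    s1 <- 1 - 0.5 * (1 - tanh(k2_t * (pmt_t - xc2_t)))
    A_t <- (bem_t - y0_t) / (1 + B_t * s1)   # so the curve peak sits near bem_t

    # extension generating parameters
    rmax_t <- clamp(0.95 + stats::rnorm(n, 0, 0.10), 0.72, 1.18)
    e_rmax_t <- 38 + 24 * trait()
    e_max_t <- e_rmax_t + 7 + 5 * trait()

    # protein composition
    ratio_t <- 1.25 + 1.5 * trait()
    glia_tot <- 100 * ratio_t / (1 + ratio_t)
    glut_tot <- 100 - glia_tot
    sh_g_hmw <- clamp(stats::rnorm(n, 0.18, 0.025), 0.10, 0.26)
    sh_g_mmw <- clamp(stats::rnorm(n, 0.12, 0.015), 0.07, 0.17)
    sh_u_hmw <- clamp(stats::rnorm(n, 0.045, 0.010), 0.02, 0.07)
    sh_u_mmw <- clamp(stats::rnorm(n, 0.21, 0.020), 0.15, 0.28)
    comp <- tibble::tibble(
      gliadin_hmw = glia_tot * sh_g_hmw,
      gliadin_mmw = glia_tot * sh_g_mmw,
      gliadin_lmw = glia_tot * (1 - sh_g_hmw - sh_g_mmw),
      glutenin_hmw = glut_tot * sh_u_hmw,
      glutenin_mmw = glut_tot * sh_u_mmw,
      glutenin_lmw = glut_tot * (1 - sh_u_hmw - sh_u_mmw)
    )

    ids <- sprintf("S%02d", seq_len(n))
    agg_curves <- vector("list", n)
    ext_curves <- vector("list", n)
    chroms <- vector("list", n)
    cce_list <- vector("list", n)
    for (i in seq_len(n)) {
      cce <- cce_params(y0 = y0_t[i], xc1 = pmt_t[i], A = A_t[i], w = w_t[i],
                        k2 = k2_t[i], xc2 = xc2_t[i], B = B_t[i],
                        k3 = k3_t[i], xc3 = xc3_t[i])
      cce_list[[i]] <- cce
      agg_curves[[i]] <- generate_aggregation_curve(
        cce, noise_sd = config$aggregation_noise_sd,
        interval = config$aggregation_interval,
        duration = config$aggregation_duration)
      ext_curves[[i]] <- generate_extension_curve(
        rmax = rmax_t[i], e_rmax = e_rmax_t[i], e_max = e_max_t[i],
        noise_sd = config$extension_noise_sd,
        interval = config$extension_interval)
      chroms[[i]] <- generate_chromatogram(
        comp[i, ], noise_sd = config$chromatogram_noise_sd)
    }
    names(agg_curves) <- names(ext_curves) <- names(chroms) <- ids

    truth <- tibble::tibble(
      sample_id = ids, true_class = classes, q = q,
      y0 = y0_t, xc1 = pmt_t, A = A_t, w = w_t, k2 = k2_t, xc2 = xc2_t,
      B = B_t, k3 = k3_t, xc3 = xc3_t, BEM_target = bem_t,
      R_max = rmax_t, E_Rmax = e_rmax_t, E_max = e_max_t,
      comp, glia_glut_ratio = ratio_t
    )

    structure(list(
      records = tibble::tibble(sample_id = ids,
                               volume_A_ml_per_g = vol_A,
                               volume_B_ml_per_g = vol_B,
                               true_class = classes),
      aggregation_curves = agg_curves,
      extension_curves = ext_curves,
      chromatograms = chroms,
      truth = truth,
      config = config
    ), class = "gluten_panel")
  })
}

#' @export
print.gluten_panel <- function(x, ...) {
  cat(sprintf("<gluten_panel> %d samples (%s)\n", nrow(x$records),
              paste(names(table(x$records$true_class)),
                    table(x$records$true_class), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export a synthetic panel as CSV files
#'
#' Writes one samples CSV (`samples.csv`), one curve CSV per sample per
#' modality (two columns with header), chromatograms as two-column CSVs
#' per extract, and the generating configuration as YAML.
#'
#' @param panel a [generate_panel()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "gluten_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(panel$records, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  for (id in panel$records$sample_id) {
    ac <- panel$aggregation_curves[[id]]
    utils::write.csv(data.frame(time_s = ac$time, torque_BU = ac$torque),
                     file.path(dir, paste0(id, "_aggregation.csv")),
                     row.names = FALSE)
    ec <- panel$extension_curves[[id]]
    utils::write.csv(data.frame(distance_mm = ec$distance, force_N = ec$force),
                     file.path(dir, paste0(id, "_extension.csv")),
                     row.names = FALSE)
    for (ex in c("gliadin", "glutenin")) {
      ch <- panel$chromatograms[[id]][[ex]]
      utils::write.csv(data.frame(retention_min = ch$retention,
                                  signal = ch$signal),
                       file.path(dir, paste0(id, "_", ex, ".csv")),
                       row.names = FALSE)
    }
  }
  cfg <- panel$config
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
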