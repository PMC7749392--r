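#' Extract the full feature table of a synthetic panel
#'
#' Runs the aggregation, extension and protein-composition feature
#' extractors over every sample of a [generate_panel()] result.
#'
#' @param panel a `gluten_panel`.
#' @param include_cce fit the Chesler-Cram model per aggregation curve and
#'   include its parameters as features (default `TRUE`; the fit dominates
#'   run time on large panels).
#' @return [tibble::tibble] with `sample_id` and one column per feature.
#' @export
extract_panel_features <- function(panel, include_cce = TRUE) {
  stopifnot(inherits(panel, "gluten_panel"))
  rows <- lapply(panel$records$sample_id, function(id) {
    agg <- extract_aggregation_features(panel$aggregation_curves[[id]],
                                        fit_model = include_cce)
    ext <- extract_extension_features(panel$extension_curves[[id]])
    ch <- panel$chromatograms[[id]]
    gl <- integrate_windows(ch$gliadin)
    gu <- integrate_windows(ch$glutenin)
    prot <- compose_composition(gl, gu)
    tibble::tibble(sample_id = id, agg, ext[, setdiff(names(ext), "ruptured")],
                   prot)
  })
  do.call(rbind, rows)
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a panel) or `"files"` (read a
#'   samples CSV and optional curve manifests).
#' @param panel a [panel_config()] (synthetic mode).
#' @param samples_csv path to a samples CSV with columns `sample_id`,
#'   `volume_A_ml_per_g`, `volume_B_ml_per_g` (files mode).
#' @param aggregation_manifest,extension_manifest optional manifest CSVs
#'   (`sample_id`, `path`) pointing at two-column curve CSVs; replicate
#'   rows per sample are feature-averaged.
#' @param chromatogram_manifest optional manifest CSV (`sample_id`,
#'   `path`, `extract`) pointing at two-column chromatogram CSVs.
#' @param feature_table optional pre-computed per-sample feature table
#'   (data frame or CSV path) injected in place of curve extraction, e.g.
#'   a transcribed supplementary table.
#' @param include_cce include Chesler-Cram fit parameters as features.
#' @param linkage,standardize,refine_iterations passed to
#'   [cluster_quality()].
#' @param alpha significance level of the correlation screen.
#' @param threshold_policy `"scaled"` sets the good/medium thresholds to
#'   75% and 25% of the maximum attainable score of the selected weight
#'   set; `"fixed"` uses `thresholds` as absolute totals (the published
#'   80/50 convention, meaningful for the published weight set).
#' @param thresholds absolute thresholds used when
#'   `threshold_policy = "fixed"`.
#' @param out_dir optional directory for CSV artifacts.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            panel = panel_config(),
                            samples_csv = NULL,
                            aggregation_manifest = NULL,
                            extension_manifest = NULL,
                            chromatogram_manifest = NULL,
                            feature_table = NULL,
                            include_cce = TRUE,
                            linkage = "complete",
                            standardize = TRUE,
                            refine_iterations = 0L,
                            alpha = 0.05,
                            threshold_policy = c("scaled", "fixed"),
                            thresholds = c(good = 80, medium = 50),
                            out_dir = NULL) {
  mode <- match.arg(mode)
  threshold_policy <- match.arg(threshold_policy)
  if (mode == "files") {
    if (is.null(samples_csv)) stop("files mode requires samples_csv")
    for (p in c(samples_csv, aggregation_manifest, extension_manifest,
                chromatogram_manifest,
                if (is.character(feature_table)) feature_table)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    for (mf in c(aggregation_manifest, extension_manifest,
                 chromatogram_manifest)) {
      man <- utils::read.csv(mf, stringsAsFactors = FALSE)
      bad <- man$path[!file.exists(man$path)]
      if (length(bad) > 0L) {
        stop("manifest ", mf, " references missing file(s): ",
             paste(utils::head(bad, 3L), collapse = ", "))
      }
    }
  } else {
    stopifnot(inherits(panel, "panel_config"))
  }
  structure(list(mode = mode, panel = panel, samples_csv = samples_csv,
                 aggregation_manifest = aggregation_manifest,
                 extension_manifest = extension_manifest,
                 chromatogram_manifest = chromatogram_manifest,
                 feature_table = feature_table,
                 include_cce = include_cce, linkage = linkage,
                 standardize = standardize,
                 refine_iterations = refine_iterations, alpha = alpha,
                 threshold_policy = threshold_policy,
                 thresholds = thresholds, out_dir = out_dir),
            class = "run_config")
}

read_curve_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "path") %in% names(man)))
  man
}

features_from_manifests <- function(config, ids) {
  feats <- NULL
  if (!is.null(config$aggregation_manifest)) {
    man <- read_curve_manifest(config$aggregation_manifest)
    rows <- lapply(split(man, man$sample_id), function(grp) {
      per <- lapply(grp$path, function(p) {
        cv <- utils::read.csv(p)
        extract_aggregation_features(aggregation_curve(cv[[1L]], cv[[2L]]),
                                     fit_model = config$include_cce)
      })
      tab <- do.call(rbind, per)
      tibble::tibble(sample_id = grp$sample_id[1L],
                     tibble::as_tibble(as.list(colMeans(tab))))
    })
    feats <- do.call(rbind, rows)
  }
  if (!is.null(config$extension_manifest)) {
    man <- read_curve_manifest(config$extension_manifest)
    rows <- lapply(split(man, man$sample_id), function(grp) {
      curves <- lapply(grp$path, function(p) {
        cv <- utils::read.csv(p)
        extension_curve(cv[[1L]], cv[[2L]])
      })
      tibble::tibble(sample_id = grp$sample_id[1L],
                     average_extension_features(curves))
    })
    ext <- do.call(rbind, rows)
    feats <- if (is.null(feats)) ext else merge(feats, ext, by = "sample_id")
  }
  if (!is.null(config$chromatogram_manifest)) {
    man <- utils::read.csv(config$chromatogram_manifest,
                           stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "path", "extract") %in% names(man)))
    rows <- lapply(split(man, man$sample_id), function(grp) {
      masses <- lapply(c("gliadin", "glutenin"), function(ex) {
        p <- grp$path[grp$extract == ex]
        if (length(p) != 1L) stop("need exactly one ", ex,
                                  " trace for sample ", grp$sample_id[1L])
        cv <- utils::read.csv(p)
        integrate_windows(chromatogram(cv[[1L]], cv[[2L]], extract = ex))
      })
      tibble::tibble(sample_id = grp$sample_id[1L],
                     compose_composition(masses[[1L]], masses[[2L]]))
    })
    prot <- do.call(rbind, rows)
    feats <- if (is.null(feats)) prot else merge(feats, prot, by = "sample_id")
  }
  if (!is.null(feats)) tibble::as_tibble(feats) else NULL
}

#' Run the quality-prediction pipeline end to end
#'
#' Sequences feature extraction, volume-based quality classification,
#' Spearman feature screening, scoring-configuration construction
#' (medium-class quantile ranges, correlation weights) and score-based
#' prediction, and evaluates prediction accuracy against the
#' cluster-assigned classes. Deterministic for identical configuration
#' (synthetic mode draws everything from the panel's `rng_seed`).
#'
#' @param config a [pipeline_config()].
#' @return Object of class `gluten_run`: list with `records` (incl.
#'   assigned class), `clusters`, `features`, `correlations`, `weights`,
#'   `scoring` (the [scoring_config()]), `scores`, `accuracy` and
#'   `summary` (class counts, between-recipe Spearman, accuracy, seed).
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(
#'   mode = "synthetic",
#'   panel = panel_config(n_samples = 16, rng_seed = 3),
#'   include_cce = FALSE))
#' run$summary
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    panel <- generate_panel(config$panel)
    records <- panel$records
    features <- extract_panel_features(panel, include_cce = config$include_cce)
  } else {
    records <- tibble::as_tibble(utils::read.csv(config$samples_csv,
                                                 stringsAsFactors = FALSE))
    stopifnot(all(c("sample_id", "volume_A_ml_per_g", "volume_B_ml_per_g")
                  %in% names(records)))
    features <- if (!is.null(config$feature_table)) {
      ft <- config$feature_table
      if (is.character(ft)) ft <- utils::read.csv(ft, stringsAsFactors = FALSE)
      tibble::as_tibble(ft)
    } else {
      features_from_manifests(config, records$sample_id)
    }
  }

  clusters <- cluster_quality(records, linkage = config$linkage,
                              standardize = config$standardize,
                              refine_iterations = config$refine_iterations)
  records$quality_class <- as.character(clusters$labels)
  sp <- spearman_cor(records$volume_A_ml_per_g, records$volume_B_ml_per_g)

  correlations <- weights <- scoring <- scores <- accuracy <- NULL
  if (!is.null(features)) {
    idx <- match(records$sample_id, features$sample_id)
    if (anyNA(idx)) {
      stop("feature table lacks sample(s): ",
           paste(records$sample_id[is.na(idx)], collapse = ", "))
    }
    features <- features[idx, , drop = FALSE]
    correlations <- correlation_table(features, records, alpha = config$alpha)
    weights <- select_scored_parameters(correlations, alpha = config$alpha,
                                        include_cce = config$include_cce)
    if (nrow(weights) == 0L) stop("no parameter passed the correlation screen")
    ranges <- medium_quantile_ranges(features, records$quality_class, weights)
    thr <- if (config$threshold_policy == "fixed") config$thresholds else {
      mx <- 20 * sum(weights$weight)
      c(good = 0.75 * mx, medium = 0.25 * mx)
    }
    scoring <- scoring_config(ranges, weights, thresholds = thr)
    scores <- score_samples(features, scoring)
    accuracy <- evaluate_accuracy(scores$predicted_class,
                                  records$quality_class)
  }

  summary <- list(
    n = nrow(records),
    class_counts = as.list(clusters$counts),
    spearman_volumes = sp$r,
    spearman_volumes_p = sp$p,
    n_scored_parameters = if (is.null(weights)) 0L else nrow(weights),
    accuracy_percent = if (is.null(accuracy)) NA_real_ else accuracy$accuracy_percent,
    seed = if (config$mode == "synthetic") config$panel$rng_seed else NA_integer_
  )

  out <- structure(list(records = records, clusters = clusters,
                        features = features, correlations = correlations,
                        weights = weights, scoring = scoring,
                        scores = scores, accuracy = accuracy,
                        summary = summary, config = config),
                   class = "gluten_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' @export
print.gluten_run <- function(x, ...) {
  cat("<gluten_run>\n")
  cat("  samples:", x$summary$n, "\n")
  cat("  class counts:",
      paste(names(x$summary$class_counts), unlist(x$summary$class_counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  Spearman(volume A, volume B) = %.3f\n",
              x$summary$spearman_volumes))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  scored parameters: %d, accuracy %.1f%%\n",
                x$summary$n_scored_parameters, x$summary$accuracy_percent))
  }
  invisible(x)
}

# materialise every stage's table as CSV plus a YAML summary
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$records, file.path(dir, "samples_classified.csv"),
                   row.names = FALSE)
  if (!is.null(run$features)) {
    utils::write.csv(run$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(run$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(run$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
    write_scoring_config(run$scoring, file.path(dir, "scoring_config.yaml"))
  }
  yaml::write_yaml(run$summary, file.path(dir, "summary.yaml"))
  invisible(dir)
}
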