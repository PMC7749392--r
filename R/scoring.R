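#' Quantile ranges of the medium quality class
#'
#' For each scored parameter, the 25% and 75% quantiles of the values in
#' the medium-labelled group define the "medium" band; values beyond the
#' band in the quality-improving direction count as good, beyond it in the
#' other direction as poor. Quantiles use linear interpolation of order
#' statistics at positions `h = (n - 1) p + 1`.
#'
#' @param features data frame of per-sample feature values (one column per
#'   scored parameter).
#' @param labels quality-class labels aligned with `features` rows; at
#'   least 3 samples must be labelled `"medium"`.
#' @param weights weight table from [select_scored_parameters()], providing
#'   the parameter list and directions.
#' @return [tibble::tibble] with columns `parameter`, `q25`, `q75`,
#'   `direction`.
#' @export
medium_quantile_ranges <- function(features, labels, weights) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels),
            all(c("parameter", "direction") %in% names(weights)))
  med <- features[labels == "medium", , drop = FALSE]
  if (nrow(med) < 3L) stop("need at least 3 medium-labelled samples")
  missing <- setdiff(weights$parameter, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks scored parameter(s): ",
         paste(missing, collapse = ", "))
  }
  qs <- vapply(weights$parameter, function(pn) {
    stats::quantile(med[[pn]], c(0.25, 0.75), names = FALSE, type = 7)
  }, numeric(2L))
  tibble::tibble(parameter = weights$parameter,
                 q25 = unname(qs[1L, ]), q75 = unname(qs[2L, ]),
                 direction = weights$direction)
}

#' Allocate quality points for one parameter value
#'
#' 20 points for values in the good band, 10 for the medium band, 0 for
#' the poor band. With direction +1 (parameter increases with quality),
#' values above `q75` score 20 and below `q25` score 0; with direction -1
#' the bands mirror. Values exactly on a boundary score 10.
#'
#' @param value parameter value(s), finite.
#' @param q25,q75 medium-band quantiles, `q25 <= q75`.
#' @param direction +1 or -1.
#' @return Integer vector of points in `{0, 10, 20}`.
#' @examples
#' allocate_points(c(1, 5, 9), q25 = 3, q75 = 7, direction = +1)  # 0 10 20
#' @export
allocate_points <- function(value, q25, q75, direction) {
  stopifnot(q25 <= q75, direction %in% c(-1, 1))
  if (any(!is.finite(value))) stop("value must be finite")
  up <- ifelse(value > q75, 20L, ifelse(value < q25, 0L, 10L))
  down <- ifelse(value < q25, 20L, ifelse(value > q75, 0L, 10L))
  if (direction > 0) up else down
}

#' Assemble a scoring configuration
#'
#' @param ranges quantile-range table from [medium_quantile_ranges()].
#' @param weights weight table from [select_scored_parameters()].
#' @param thresholds named numeric vector `c(good = ..., medium = ...)`:
#'   totals strictly greater than `good` classify as good, greater than
#'   `medium` as medium, otherwise poor.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(ranges, weights,
                           thresholds = c(good = 80, medium = 50)) {
  stopifnot(all(c("parameter", "q25", "q75", "direction") %in% names(ranges)),
            all(c("parameter", "weight") %in% names(weights)),
            all(c("good", "medium") %in% names(thresholds)),
            thresholds[["good"]] > thresholds[["medium"]])
  if (!setequal(ranges$parameter, weights$parameter)) {
    stop("ranges and weights must cover the same parameters")
  }
  structure(list(ranges = ranges,
                 weights = weights[match(ranges$parameter, weights$parameter), ],
                 thresholds = thresholds),
            class = "scoring_config")
}

#' Maximum attainable total of a scoring configuration
#' @param config a [scoring_config()].
#' @return `20 * sum(weights)`.
#' @export
max_score <- function(config) {
  stopifnot(inherits(config, "scoring_config"))
  20 * sum(config$weights$weight)
}

#' Score one sample
#'
#' Allocates 0/10/20 points per scored parameter from the quantile bands,
#' multiplies each by the parameter's correlation weight, and sums.
#'
#' @param features one-row data frame (or named list/vector) holding every
#'   scored parameter.
#' @param config a [scoring_config()].
#' @return List with `total` and `breakdown` (tibble: parameter, value,
#'   points, weight, contribution).
#' @export
score_sample <- function(features, config) {
  stopifnot(inherits(config, "scoring_config"))
  feats <- as.list(features)
  missing <- setdiff(config$ranges$parameter, names(feats))
  if (length(missing) > 0L) {
    stop("sample lacks scored parameter(s): ", paste(missing, collapse = ", "))
  }
  rg <- config$ranges
  vals <- vapply(rg$parameter, function(pn) as.numeric(feats[[pn]][1L]),
                 numeric(1L))
  pts <- vapply(seq_len(nrow(rg)), function(i) {
    allocate_points(vals[i], rg$q25[i], rg$q75[i], rg$direction[i])
  }, integer(1L))
  w <- config$weights$weight
  contrib <- pts * w
  list(total = sum(contrib),
       breakdown = tibble::tibble(parameter = rg$parameter, value = vals,
                                  points = pts, weight = w,
                                  contribution = contrib))
}

#' Classify a score total into a quality class
#'
#' Totals strictly greater than the good threshold classify as good,
#' strictly greater than the medium threshold as medium, otherwise poor
#' (boundary totals resolve downward).
#'
#' @param total numeric score total(s), non-negative.
#' @param thresholds named vector `c(good = 80, medium = 50)`.
#' @return Character vector of `"good"`, `"medium"`, `"poor"`.
#' @examples
#' classify_score(c(85.8, 75.6, 0))   # good medium poor
#' @export
classify_score <- function(total, thresholds = c(good = 80, medium = 50)) {
  stopifnot(all(total >= 0), thresholds[["good"]] > thresholds[["medium"]])
  ifelse(total > thresholds[["good"]], "good",
         ifelse(total > thresholds[["medium"]], "medium", "poor"))
}

#' Score a whole feature table
#'
#' @param features data frame with `sample_id` plus all scored parameters.
#' @param config a [scoring_config()].
#' @return [tibble::tibble] with `sample_id`, one points column per
#'   parameter (`points_<parameter>`), `total` and `predicted_class`.
#' @export
score_samples <- function(features, config) {
  stopifnot(is.data.frame(features), "sample_id" %in% names(features))
  res <- lapply(seq_len(nrow(features)), function(i) {
    sc <- score_sample(features[i, , drop = FALSE], config)
    pts <- stats::setNames(as.list(sc$breakdown$points),
                           paste0("points_", sc$breakdown$parameter))
    tibble::tibble(sample_id = features$sample_id[i],
                   tibble::as_tibble(pts), total = sc$total)
  })
  out <- do.call(rbind, res)
  out$predicted_class <- classify_score(out$total, config$thresholds)
  out
}

#' Prediction accuracy against reference classes
#'
#' Exact-match fraction between predicted and reference quality classes,
#' reported as a percentage to one decimal, with the confusion matrix.
#'
#' @param predicted,reference class label vectors.
#' @param sample_id optional ids; when given, both vectors must be named
#'   consistently and are matched by id.
#' @return List with `accuracy_percent`, `n_correct`, `n`, `confusion`.
#' @export
evaluate_accuracy <- function(predicted, reference, sample_id = NULL) {
  if (!is.null(sample_id)) {
    stopifnot(length(predicted) == length(sample_id))
    if (length(intersect(names(reference), sample_id)) == 0L &&
        length(reference) != length(predicted)) {
      stop("no overlapping sample ids between predictions and reference")
    }
    if (!is.null(names(reference))) {
      idx <- match(sample_id, names(reference))
      if (all(is.na(idx))) stop("no overlapping sample ids")
      reference <- reference[idx]
    }
  }
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ")
  }
  lv <- c("good", "medium", "poor")
  ok <- as.character(predicted) == as.character(reference)
  n <- length(ok)
  list(accuracy_percent = round(100 * sum(ok) / n, 1L),
       n_correct = sum(ok), n = n,
       confusion = table(predicted = factor(predicted, lv),
                         reference = factor(reference, lv)))
}

#' Write / read a scoring configuration as YAML
#'
#' Round-trips the quantile ranges, weights and thresholds through a
#' single YAML file.
#'
#' @param config a [scoring_config()].
#' @param path file path.
#' @return `read_scoring_config` returns a [scoring_config()].
#' @export
write_scoring_config <- function(config, path) {
  stopifnot(inherits(config, "scoring_config"))
  yaml::write_yaml(list(
    ranges = lapply(seq_len(nrow(config$ranges)), function(i)
      as.list(config$ranges[i, ])),
    weights = lapply(seq_len(nrow(config$weights)), function(i)
      as.list(config$weights[i, c("parameter", "weight", "direction")])),
    thresholds = as.list(config$thresholds)
  ), path)
  invisible(path)
}

#' @rdname write_scoring_config
#' @export
read_scoring_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ranges <- do.call(rbind, lapply(raw$ranges, tibble::as_tibble))
  weights <- do.call(rbind, lapply(raw$weights, tibble::as_tibble))
  scoring_config(ranges, weights,
                 thresholds = unlist(raw$thresholds))
}
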