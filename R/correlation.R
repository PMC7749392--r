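#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' p-value from the t-distribution approximation on `n - 2` degrees of
#' freedom. Pairs with missing values are dropped (pairwise-complete).
#'
#' @param x,y numeric vectors of equal length (at least 4 complete pairs).
#' @return List with `r` (Spearman coefficient), `p` (two-sided p-value),
#'   `n` (complete pairs used) and logical `constant` (TRUE when either
#'   input is constant, in which case `r` and `p` are `NA`).
#' @examples
#' spearman_cor(1:10, (1:10)^3)   # r = 1: invariant to monotone transforms
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, constant = TRUE))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, constant = FALSE)
}

# canonical feature-name -> method family lookup
parameter_family <- function(parameter) {
  agg <- c("BEM", "PMT", "peak30", "peak180", "peak30_peak180",
           "y0", "xc1", "A", "w", "k2", "xc2", "B", "k3", "xc3")
  ext <- c("R_max", "E_Rmax", "A_Rmax", "E_max", "A_max",
           "E_max_R_max", "E_Rmax_R_max")
  prot <- c("gliadin_hmw", "gliadin_mmw", "gliadin_lmw", "gliadin_total",
            "glutenin_hmw", "glutenin_mmw", "glutenin_lmw", "glutenin_total",
            "glia_glut_ratio")
  diag <- c("r_squared", "ruptured")
  out <- rep("other", length(parameter))
  out[parameter %in% agg] <- "aggregation"
  out[parameter %in% ext] <- "extension"
  out[parameter %in% prot] <- "protein"
  out[parameter %in% diag] <- "diagnostic"
  out
}

#' Feature-volume correlation table
#'
#' Spearman correlation of every feature column against both specific
#' volumes, with significance, in the shape of a published correlation
#' matrix: one row per parameter, coefficients and p-values for recipes A
#' and B, and a flag for parameters significant in both.
#'
#' @param features data frame with `sample_id` plus numeric feature
#'   columns (diagnostic columns such as `r_squared` are dropped).
#' @param volumes data frame with `sample_id`, `volume_A_ml_per_g`,
#'   `volume_B_ml_per_g`.
#' @param alpha significance level (default 0.05).
#' @return [tibble::tibble] with columns `parameter`, `family`, `r_A`,
#'   `p_A`, `r_B`, `p_B`, `n`, `significant_both`.
#' @export
correlation_table <- function(features, volumes, alpha = 0.05) {
  stopifnot(is.data.frame(features), is.data.frame(volumes),
            "sample_id" %in% names(features),
            all(c("sample_id", "volume_A_ml_per_g", "volume_B_ml_per_g")
                %in% names(volumes)))
  merged <- merge(features, volumes[, c("sample_id", "volume_A_ml_per_g",
                                        "volume_B_ml_per_g")],
                  by = "sample_id")
  if (nrow(merged) < 4L) stop("fewer than 4 samples with matching ids")
  cols <- setdiff(names(features), "sample_id")
  cols <- cols[vapply(features[cols], is.numeric, logical(1L))]
  cols <- cols[parameter_family(cols) != "diagnostic"]
  rows <- lapply(cols, function(cl) {
    sa <- suppressWarnings(spearman_cor(merged[[cl]], merged$volume_A_ml_per_g))
    sb <- suppressWarnings(spearman_cor(merged[[cl]], merged$volume_B_ml_per_g))
    tibble::tibble(parameter = cl, family = parameter_family(cl),
                   r_A = sa$r, p_A = sa$p, r_B = sb$r, p_B = sb$p,
                   n = min(sa$n, sb$n),
                   significant_both = isTRUE(sa$p <= alpha) && isTRUE(sb$p <= alpha))
  })
  do.call(rbind, rows)
}

#' Select scored parameters and their weights
#'
#' Keeps the parameters that correlate significantly with the specific
#' volumes of both recipes, restricted to the rapid-test families
#' (aggregation and extension; protein-composition parameters are screened
#' but not scored). Each kept parameter gets weight `mean(|r_A|, |r_B|)`
#' and direction `sign(r_A)`; a parameter whose two coefficients disagree
#' in sign is dropped with a warning.
#'
#' @param entries correlation table as from [correlation_table()] (or the
#'   packaged [reference_correlations()]); needs columns `parameter`,
#'   `family`, `r_A`, `p_A`, `r_B`, `p_B`.
#' @param alpha per-recipe significance level (default 0.05).
#' @param families families eligible for scoring.
#' @param include_cce keep the Chesler-Cram fit parameters (`y0` ... `xc3`)
#'   among the candidates (default `TRUE`).
#' @return [tibble::tibble] with columns `parameter`, `weight`,
#'   `direction` (+1/-1), `r_A`, `r_B`.
#' @examples
#' select_scored_parameters(reference_correlations())
#' @export
select_scored_parameters <- function(entries, alpha = 0.05,
                                     families = c("aggregation", "extension"),
                                     include_cce = TRUE) {
  stopifnot(is.data.frame(entries),
            all(c("parameter", "family", "r_A", "p_A", "r_B", "p_B")
                %in% names(entries)))
  keep <- entries$family %in% families &
    !is.na(entries$p_A) & entries$p_A <= alpha &
    !is.na(entries$p_B) & entries$p_B <= alpha
  if (!include_cce) {
    keep <- keep & !(entries$parameter %in%
                       c("y0", "xc1", "A", "w", "k2", "xc2", "B", "k3", "xc3"))
  }
  sel <- entries[keep, , drop = FALSE]
  agree <- sign(sel$r_A) == sign(sel$r_B)
  if (any(!agree)) {
    warning("dropping parameter(s) with sign disagreement between recipes: ",
            paste(sel$parameter[!agree], collapse = ", "))
    sel <- sel[agree, , drop = FALSE]
  }
  tibble::tibble(parameter = sel$parameter,
                 weight = (abs(sel$r_A) + abs(sel$r_B)) / 2,
                 direction = sign(sel$r_A),
                 r_A = sel$r_A, r_B = sel$r_B)
}
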