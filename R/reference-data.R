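#' Packaged 46-sample microbaking reference panel
#'
#' Published specific volumes (ml/g) of 46 commercial vital gluten samples
#' in two microbaking recipes (A and B), together with the quality-class
#' labels assigned to them by hierarchical clustering of those volumes.
#' Ships with the package as a plain CSV and serves as the regression
#' fixture for the classification module.
#'
#' @return [tibble::tibble] with columns `sample_id`, `volume_A_ml_per_g`,
#'   `volume_B_ml_per_g`, `quality_class`.
#' @examples
#' vols <- reference_volumes()
#' table(vols$quality_class)
#' @export
reference_volumes <- function() {
  path <- system.file("extdata", "reference_volumes.csv",
                      package = "glutenscore", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged feature-volume Spearman coefficients for the reference panel
#'
#' Published Spearman correlation coefficients (and p-values, where the
#' source reports them; `NA` marks non-significant entries reported only
#' as "n.s.") between each measured parameter and the specific volumes of
#' recipes A and B on the 46-sample reference panel. Entries printed as
#' "<= 0.001" are stored as 0.001. This table drives the published scoring
#' weights via [select_scored_parameters()].
#'
#' @return [tibble::tibble] with columns `parameter`, `family`, `r_A`,
#'   `p_A`, `r_B`, `p_B`.
#' @examples
#' w <- select_scored_parameters(reference_correlations())
#' sum(w$weight) * 20   # maximum attainable score, about 113.5
#' @export
reference_correlations <- function() {
  path <- system.file("extdata", "reference_correlations.csv",
                      package = "glutenscore", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
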