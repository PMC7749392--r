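#' GP-HPLC chromatogram
#'
#' Absorbance-vs-retention-time trace of one Osborne extract (gliadin or
#' glutenin) separated by gel-permeation HPLC. The trace must cover at
#' least the 6.0-13.0 min elution range used for quantitation.
#'
#' @param retention retention time in minutes, strictly increasing.
#' @param signal detector signal (absorbance units), non-negative.
#' @param extract `"gliadin"` or `"glutenin"`.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(retention, signal,
                         extract = c("gliadin", "glutenin")) {
  extract <- match.arg(extract)
  stopifnot(is.numeric(retention), is.numeric(signal))
  if (length(retention) != length(signal)) stop("retention and signal lengths differ")
  if (anyNA(retention) || anyNA(signal)) stop("chromatogram contains NA")
  if (any(diff(retention) <= 0)) stop("retention must be strictly increasing")
  if (retention[1L] > 6.0 || retention[length(retention)] < 13.0) {
    stop("chromatogram must cover at least [6.0, 13.0] min")
  }
  if (any(signal < 0)) stop("signal must be non-negative")
  structure(list(retention = as.numeric(retention),
                 signal = as.numeric(signal), extract = extract),
            class = "chromatogram")
}

#' Molecular-weight retention windows
#'
#' Default elution windows, in minutes, for the high/medium/low
#' molecular-weight fractions of each extract. Within one extract the
#' windows are contiguous and share boundaries, so integration over them
#' partitions the 6.0-13.0 min range exactly.
#'
#' @return Named list with elements `gliadin` and `glutenin`, each a
#'   data frame with columns `fraction`, `start`, `end`.
#' @export
retention_windows <- function() {
  list(
    gliadin = data.frame(fraction = c("hmw", "mmw", "lmw"),
                         start = c(6.0, 8.1, 9.1),
                         end = c(8.1, 9.1, 13.0)),
    glutenin = data.frame(fraction = c("hmw", "mmw", "lmw"),
                          start = c(6.0, 7.4, 8.6),
                          end = c(7.4, 8.6, 13.0))
  )
}

#' Fit a mass calibration line to reference-protein standards
#'
#' Ordinary least squares of peak area on injected mass, as used with a
#' reference gliadin (PWG-gliadin) dilution series. The intercept is
#' retained rather than forced through the origin.
#'
#' @param standards data frame with columns `mass_ug` and `area`.
#' @return List with `slope` (area per ug), `intercept` (area) and
#'   `r_squared`; class `calibration_model`.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mass_ug", "area") %in% names(standards)))
  m <- standards$mass_ug
  a <- standards$area
  if (length(unique(m)) < 2L) stop("calibration needs at least 2 distinct masses")
  if (any(m < 11.6 | m > 46.6)) {
    warning("calibration masses outside the usual 11.6-46.6 ug standard range")
  }
  fit <- stats::lm(a ~ m)
  co <- stats::coef(fit)
  sst <- sum((a - mean(a))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2),
            class = "calibration_model")
}

#' Identity calibration (area = mass)
#'
#' Convenience model for synthetic chromatograms whose trace is generated
#' directly on the mass scale.
#' @return A `calibration_model` with slope 1, intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(slope = 1, intercept = 0, r_squared = 1),
            class = "calibration_model")
}

#' Integrate a chromatogram over molecular-weight windows
#'
#' Trapezoidal area of the (optionally baseline-corrected) signal over each
#' retention window, with boundary ordinates obtained by linear
#' interpolation, converted to protein mass through the inverse calibration
#' line. Negative masses (possible with a positive calibration intercept)
#' are clamped to zero with a warning.
#'
#' @param chrom a [chromatogram()].
#' @param windows window set as from [retention_windows()]; the element
#'   matching `chrom$extract` is used.
#' @param calibration a `calibration_model` from [fit_calibration()] or
#'   [identity_calibration()].
#' @param baseline_correct subtract the minimum signal over the full
#'   quantitation range before integrating (default `TRUE`).
#' @return Named numeric vector of masses (ug) for `hmw`, `mmw`, `lmw`.
#' @export
integrate_windows <- function(chrom, windows = retention_windows(),
                              calibration = identity_calibration(),
                              baseline_correct = TRUE) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(calibration, "calibration_model"))
  win <- windows[[chrom$extract]]
  if (is.null(win)) stop("no windows defined for extract ", chrom$extract)
  lo <- min(win$start)
  hi <- max(win$end)
  if (lo < chrom$retention[1L] || hi > chrom$retention[length(chrom$retention)]) {
    stop("retention windows extend beyond the recorded trace")
  }
  sig <- chrom$signal
  if (isTRUE(baseline_correct)) {
    inrange <- chrom$retention >= lo & chrom$retention <= hi
    sig <- sig - min(sig[inrange])
  }
  areas <- mapply(function(s, e) trapz_window(chrom$retention, sig, s, e),
                  win$start, win$end)
  masses <- (areas - calibration$intercept) / calibration$slope
  if (any(masses < 0)) {
    warning("negative window mass clamped to 0")
    masses <- pmax(masses, 0)
  }
  stats::setNames(masses, win$fraction)
}

#' Compose relative protein fractions from window masses
#'
#' Expresses the six window masses (three per extract) as percentages of
#' the grand total, together with the gliadin and glutenin totals and
#' their ratio.
#'
#' @param gliadin_masses,glutenin_masses named (or ordered hmw, mmw, lmw)
#'   non-negative mass vectors on a common scale.
#' @return One-row [tibble::tibble] with columns `gliadin_hmw`,
#'   `gliadin_mmw`, `gliadin_lmw`, `glutenin_hmw`, `glutenin_mmw`,
#'   `glutenin_lmw` (percent of total gluten protein), `gliadin_total`,
#'   `glutenin_total` and `glia_glut_ratio` (NA with a warning if the
#'   glutenin total is zero).
#' @examples
#' compose_composition(c(10.78, 0, 0), c(0, 0, 9.22))
#' @export
compose_composition <- function(gliadin_masses, glutenin_masses) {
  g <- as.numeric(gliadin_masses)
  u <- as.numeric(glutenin_masses)
  stopifnot(length(g) == 3L, length(u) == 3L)
  if (any(!is.finite(c(g, u))) || any(c(g, u) < 0)) {
    stop("masses must be finite and non-negative")
  }
  total <- sum(g) + sum(u)
  if (total <= 0) stop("grand total mass is zero")
  fr <- 100 * c(g, u) / total
  gl_tot <- sum(fr[1:3])
  gu_tot <- sum(fr[4:6])
  ratio <- if (gu_tot > 0) gl_tot / gu_tot else {
    warning("zero glutenin total: GLIA/GLUT ratio undefined")
    NA_real_
  }
  tibble::tibble(
    gliadin_hmw = fr[1L], gliadin_mmw = fr[2L], gliadin_lmw = fr[3L],
    glutenin_hmw = fr[4L], glutenin_mmw = fr[5L], glutenin_lmw = fr[6L],
    gliadin_total = gl_tot, glutenin_total = gu_tot,
    glia_glut_ratio = ratio
  )
}
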