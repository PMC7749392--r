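#' Microscale extension curve
#'
#' Container for a force-distance trace from a microscale dough/gluten
#' extension test (Kieffer-rig style). Distances in mm from 0, forces in N.
#'
#' @param distance mm, strictly increasing, starting at 0; sampling
#'   interval at most 1 mm.
#' @param force N, non-negative, same length as `distance`.
#' @return An object of class `extension_curve`.
#' @examples
#' curve <- generate_extension_curve(rmax = 1, e_rmax = 50, e_max = 70,
#'                                   noise_sd = 0)
#' extract_extension_features(curve)
#' @export
extension_curve <- function(distance, force) {
  stopifnot(is.numeric(distance), is.numeric(force))
  if (length(distance) != length(force)) stop("distance and force lengths differ")
  if (length(distance) < 10L) stop("extension curve needs at least 10 points")
  if (anyNA(distance) || anyNA(force)) stop("extension curve contains NA")
  if (any(diff(distance) <= 0)) stop("distance must be strictly increasing")
  if (abs(distance[1L]) > 1e-9) stop("distance must start at 0")
  if (any(diff(distance) > 1 + 1e-9)) stop("sampling interval must be <= 1 mm")
  if (any(force < 0)) stop("force must be non-negative")
  structure(list(distance = as.numeric(distance), force = as.numeric(force)),
            class = "extension_curve")
}

#' @export
print.extension_curve <- function(x, ...) {
  cat(sprintf("<extension_curve> %d points, d = [0, %g] mm, force max %.3f N\n",
              length(x$distance), x$distance[length(x$distance)], max(x$force)))
  invisible(x)
}

#' Detect the rupture point of an extension curve
#'
#' The rupture distance `E_max` is the distance of the last point before
#' the first post-peak drop whose sample-to-sample force decrease exceeds
#' `break_sensitivity`. "Post-peak" means after the global force maximum.
#' If no such drop exists (e.g. a monotonically rising ramp), the final
#' distance is returned with `ruptured = FALSE`.
#'
#' @param curve an [extension_curve()].
#' @param break_sensitivity per-sample force drop that counts as rupture,
#'   N; default 0.020 N (the usual texture-analyzer break sensitivity).
#' @return List with `E_max` (mm) and logical `ruptured`.
#' @export
detect_rupture <- function(curve, break_sensitivity = 0.020) {
  stopifnot(inherits(curve, "extension_curve"), break_sensitivity > 0)
  f <- curve$force
  d <- curve$distance
  ipeak <- which.max(f)
  drops <- which(diff(f) < -break_sensitivity)
  drops <- drops[drops >= ipeak]
  if (length(drops) == 0L) {
    return(list(E_max = d[length(d)], ruptured = FALSE))
  }
  list(E_max = d[drops[1L]], ruptured = TRUE)
}

#' Extract features from a microscale extension curve
#'
#' Computes the maximum resistance to extension `R_max` (N), its distance
#' `E_Rmax` (mm, earliest tie), the trapezoidal area to that distance
#' `A_Rmax` (N*mm = mJ), the rupture distance `E_max` from
#' [detect_rupture()], the total area `A_max` over `[0, E_max]` (mJ) and
#' the ratios `E_max/R_max` and `E_Rmax/R_max` (mm/N).
#'
#' @param curve an [extension_curve()].
#' @param break_sensitivity passed to [detect_rupture()].
#' @return One-row [tibble::tibble] with columns `R_max`, `E_Rmax`,
#'   `A_Rmax`, `E_max`, `A_max`, `E_max_R_max`, `E_Rmax_R_max`, `ruptured`.
#' @export
extract_extension_features <- function(curve, break_sensitivity = 0.020) {
  stopifnot(inherits(curve, "extension_curve"))
  f <- curve$force
  d <- curve$distance
  ipeak <- which.max(f)
  r_max <- f[ipeak]
  e_rmax <- d[ipeak]
  rupt <- detect_rupture(curve, break_sensitivity)
  a_rmax <- trapz_window(d, f, 0, e_rmax)
  a_max <- trapz_window(d, f, 0, rupt$E_max)
  tibble::tibble(
    R_max = r_max,
    E_Rmax = e_rmax,
    A_Rmax = a_rmax,
    E_max = rupt$E_max,
    A_max = a_max,
    E_max_R_max = rupt$E_max / r_max,
    E_Rmax_R_max = e_rmax / r_max,
    ruptured = rupt$ruptured
  )
}

#' Average extension features over replicate curves
#'
#' Extension tests are usually run in several replicates per sample; the
#' per-sample value of each feature is the arithmetic mean over replicates.
#'
#' @param curves list of [extension_curve()] objects.
#' @param break_sensitivity passed to [extract_extension_features()].
#' @return One-row tibble of averaged features (the `ruptured` column is
#'   the fraction of replicates that ruptured).
#' @export
average_extension_features <- function(curves, break_sensitivity = 0.020) {
  stopifnot(length(curves) >= 1L)
  rows <- lapply(curves, extract_extension_features,
                 break_sensitivity = break_sensitivity)
  tab <- do.call(rbind, rows)
  tibble::as_tibble(as.list(colMeans(as.data.frame(lapply(tab, as.numeric)))))
}
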