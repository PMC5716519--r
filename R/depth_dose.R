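# Depth-dose metrics used for beam-quality matching: dmax, %dd(d), the
# TG-51 quality specifier %dd(10)x, surface dose at 2 mm, and two curve
# comparison tools (percent difference and the 1D gamma index).

#' Normalize a depth-dose curve to 100% at its maximum
#'
#' @param curve A [depth_dose_curve()].
#' @return The curve scaled so `max(doses) == 100`, with the `normalized`
#'   flag set. Idempotent.
#' @export
normalize_pdd <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  m <- max(curve$doses)
  if (m <= 0) stop("all-zero depth-dose curve cannot be normalized")
  depth_dose_curve(curve$depths, curve$doses * (100 / m), normalized = TRUE)
}

#' Depth of maximum dose
#'
#' Finds the discrete dose maximum and refines the depth with a 3-point
#' parabolic fit through the bracketing samples. A maximum at the first or
#' last sample triggers a warning (buildup scans may start below dmax) and
#' the sample depth is returned unrefined.
#'
#' @param curve A [depth_dose_curve()].
#' @return dmax in cm.
#' @export
find_dmax <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  i <- which.max(curve$doses)
  n <- length(curve$depths)
  if (i == 1 || i == n) {
    warning("dose maximum at the boundary of the scanned depth range; returning the sample depth")
    return(curve$depths[i])
  }
  parabolic_vertex(curve$depths[(i - 1):(i + 1)], curve$doses[(i - 1):(i + 1)])
}

#' Percent depth dose at a given depth
#'
#' Linear interpolation of the normalized curve.
#'
#' @param curve A normalized [depth_dose_curve()] (see [normalize_pdd()]).
#' @param depth Depth in cm, within the scanned range.
#' @return %dd at `depth` (vectorized over `depth`).
#' @export
pdd_at <- function(curve, depth) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (!curve$normalized) stop("curve must be normalized first (normalize_pdd)")
  interp_dose(curve$depths, curve$doses, depth, what = "depth")
}

#' Beam-quality specifier %dd(10)x
#'
#' For nominal energies at or below 10 MV the photon component of the
#' percent depth dose at 10 cm equals %dd(10) itself (no
#' electron-contamination correction is needed at these energies); the
#' lead-foil protocol required above 10 MV is not supported.
#'
#' @param curve A normalized [depth_dose_curve()] covering 10 cm.
#' @param nominal_mv Nominal accelerating potential in MV (must be <= 10).
#' @return %dd(10)x in percent.
#' @export
pdd10x <- function(curve, nominal_mv = 6) {
  if (nominal_mv > 10)
    stop("unsupported energy: %dd(10)x above 10 MV requires the lead-foil photon-component protocol")
  pdd_at(curve, 10)
}

#' Surface dose (2 mm depth)
#'
#' The shallowest depth routinely measured with a plane-parallel chamber is
#' 2 mm; the %dd there is reported as the surface dose.
#'
#' @param curve A normalized [depth_dose_curve()] whose shallowest sample is
#'   at or above 2 mm depth.
#' @return %dd(0.2 cm) in percent.
#' @export
surface_dose <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (min(curve$depths) > 0.2)
    stop("insufficient buildup data: shallowest sample deeper than 2 mm")
  pdd_at(curve, 0.2)
}

#' Pointwise percent difference between two normalized curves
#'
#' Differences are in percentage points of the normalized (%dd) scale:
#' `a - b` evaluated on `grid`.
#'
#' @param curve_a,curve_b Normalized [depth_dose_curve()]s.
#' @param grid Depths in cm, within both curves' ranges.
#' @return Numeric vector of per-depth differences (percentage points).
#' @export
percent_difference <- function(curve_a, curve_b, grid) {
  pdd_at(curve_a, grid) - pdd_at(curve_b, grid)
}

#' One-dimensional gamma index
#'
#' For each reference sample r, `gamma(r)` is the minimum over a dense
#' resampling e of the evaluated curve of
#' `sqrt((dose_e - dose_r)^2 / dose_crit^2 + (x_e - x_r)^2 / dist_crit^2)`,
#' with the dose difference expressed as a percent of the reference maximum
#' (global normalization). Works on depth-dose curves or lateral profiles;
#' the axis is converted to mm internally.
#'
#' @param reference,evaluated [depth_dose_curve()]s or [beam_profile()]s on
#'   overlapping ranges.
#' @param dose_crit Dose criterion in percent of the reference maximum
#'   (default 1).
#' @param dist_crit Distance-to-agreement criterion in mm (default 1).
#' @param search_step Spacing of the dense evaluated-curve search grid in mm
#'   (default 0.01).
#' @return An object of class `gamma_result`: list with `gamma` (per
#'   reference point), `positions` (mm), `pass_fraction` (fraction with
#'   gamma <= 1), `dose_criterion`, `distance_criterion`.
#' @export
gamma_1d <- function(reference, evaluated, dose_crit = 1, dist_crit = 1,
                     search_step = 0.01) {
  if (dose_crit <= 0 || dist_crit <= 0) stop("criteria must be > 0")
  ax <- function(obj) {
    if (inherits(obj, "beam_profile")) list(x = obj$positions * 10, d = obj$doses)
    else if (inherits(obj, "depth_dose_curve")) list(x = obj$depths * 10, d = obj$doses)
    else stop("gamma_1d expects beam_profile or depth_dose_curve inputs")
  }
  r <- ax(reference); e <- ax(evaluated)
  lo <- max(min(r$x), min(e$x)); hi <- min(max(r$x), max(e$x))
  if (hi <= lo) stop("reference and evaluated ranges do not overlap")
  dose_scale <- dose_crit / 100 * max(r$d)   # absolute dose criterion
  sel <- r$x >= lo & r$x <= hi
  xr <- r$x[sel]; dr <- r$d[sel]
  grid <- seq(min(e$x), max(e$x), by = search_step)
  de <- stats::approx(e$x, e$d, xout = grid)$y
  g <- vapply(seq_along(xr), function(i) {
    # gamma is bounded by its value at zero offset, so the search window
    # |dx| <= dist_crit * that bound cannot exclude the minimizer
    d0 <- abs(stats::approx(e$x, e$d, xout = min(max(xr[i], min(e$x)), max(e$x)))$y - dr[i]) / dose_scale
    w <- dist_crit * (d0 + 1e-9) + search_step
    j <- which(grid >= xr[i] - w & grid <= xr[i] + w)
    min(sqrt(((de[j] - dr[i]) / dose_scale)^2 + ((grid[j] - xr[i]) / dist_crit)^2))
  }, numeric(1))
  structure(list(gamma = g, positions = xr,
                 pass_fraction = mean(g <= 1),
                 dose_criterion = dose_crit, distance_criterion = dist_crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d points, %.3g%%/%.3g mm: pass %.1f%%, max gamma %.3f\n",
              length(x$gamma), x$dose_criterion, x$distance_criterion,
              100 * x$pass_fraction, max(x$gamma)))
  invisible(x)
}
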