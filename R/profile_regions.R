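# Reference-beam-independent description of unflattened profiles.
#
# The conventional 80/50/20 delineation of a flattened profile normalizes to
# the central-axis dose; a cone-shaped FFF profile has no plateau to
# normalize to. The method implemented here takes the dose at the edge
# inflection point (maximum lateral gradient) and defines the reference dose
# as twice that value: for a sigmoidal edge the inflection sits at half the
# local plateau, so the 50%-of-reference points recover the conventional
# field edges without any flattened-beam data.

# moving average with shrinking window at the ends; w odd
moving_average <- function(d, w) {
  if (w <= 1) return(d)
  n <- length(d)
  h <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(d[lo:hi])
  }, numeric(1))
}

# central differences on a possibly nonuniform grid
central_diff <- function(x, d) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (d[2] - d[1]) / (x[2] - x[1])
  g[n] <- (d[n] - d[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) g[2:(n - 1)] <- (d[3:n] - d[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

# vertex of the parabola through (x1,y1),(x2,y2),(x3,y3); falls back to x2
# when the fit is degenerate or the vertex leaves the bracket
parabolic_vertex <- function(x, y) {
  X <- cbind(1, x, x^2)
  co <- tryCatch(solve(X, y), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] == 0) return(unname(x[2]))
  v <- unname(-co[2] / (2 * co[3]))
  if (v < min(x) || v > max(x)) unname(x[2]) else v
}

pick_extremum <- function(idx, score, x, center, tie) {
  best <- max(score[idx])
  cand <- idx[score[idx] >= best - 1e-12 * max(abs(best), 1)]
  if (length(cand) > 1) {
    if (tie != "first-from-center")
      stop("multiple equal derivative extrema on one side; ",
           "use tie = \"first-from-center\" to break toward the field centre")
    cand <- cand[which.min(abs(x[cand] - center))]
  }
  cand
}

#' Locate the edge inflection points of a profile
#'
#' Finds, on each side of the peak, the position of maximum lateral dose
#' gradient (`|dD/dx|`). The derivative is estimated by central differences
#' on an optionally moving-average-smoothed copy of the profile; the discrete
#' extremum is refined to sub-grid accuracy by a parabolic fit through the
#' three bracketing samples. The dose at the inflection is read from the raw
#' (unsmoothed) profile by linear interpolation.
#'
#' @param profile A [beam_profile()] spanning both field edges (dose rises
#'   then falls).
#' @param smooth_window Odd number of samples for the pre-differentiation
#'   moving average (default 5; 1 disables smoothing).
#' @param tie `"error"` (default) to fail on exactly tied derivative extrema,
#'   or `"first-from-center"` to take the tied sample nearest the field
#'   centre (outer tails can hold noise-induced slope spikes).
#' @return A list with elements `left` and `right`, each a list
#'   `(side, position, dose, slope_magnitude)`.
#' @export
find_inflections <- function(profile, smooth_window = 5,
                             tie = c("error", "first-from-center")) {
  stopifnot(inherits(profile, "beam_profile"))
  tie <- match.arg(tie)
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be an odd positive integer")
  x <- profile$positions
  d_raw <- profile$doses
  d <- moving_average(d_raw, smooth_window)
  ipk <- which.max(d)
  if (ipk <= 2 || ipk >= length(x) - 1)
    stop("profile has no rising and falling edge (peak at the boundary); cannot locate inflections")
  g <- central_diff(x, d)
  center <- x[ipk]
  one_side <- function(idx, side) {
    score <- abs(g)
    i <- pick_extremum(idx, score, x, center, tie)
    if (score[i] <= 0)
      stop("flat profile on the ", side, " side; no inflection")
    # refine |dD/dx| extremum with a 3-point parabola on the derivative
    pos <- if (i > 1 && i < length(x))
      parabolic_vertex(x[(i - 1):(i + 1)], score[(i - 1):(i + 1)]) else x[i]
    list(side = side,
         position = pos,
         dose = interp_dose(x, d_raw, pos),
         slope_magnitude = score[i])
  }
  list(left = one_side(seq_len(ipk), "left"),
       right = one_side(ipk:length(x), "right"))
}

#' Reference dose of an unflattened profile
#'
#' Twice the dose at the edge inflection point. With `combine = "mean"`
#' (default) the two side inflection doses are averaged into a single
#' reference; with `combine = "per_side"` a pair is returned and each value
#' is meant for level crossings on its own side.
#'
#' @param profile A [beam_profile()].
#' @param inflections Result of [find_inflections()]; computed if missing.
#' @param combine `"mean"` or `"per_side"`.
#' @param ... Passed to [find_inflections()] when `inflections` is missing.
#' @return A single dose (mean mode) or named numeric
#'   `c(left = , right = )` (per-side mode), in the profile's dose units.
#' @export
reference_dose <- function(profile, inflections = NULL,
                           combine = c("mean", "per_side"), ...) {
  combine <- match.arg(combine)
  if (is.null(inflections)) inflections <- find_inflections(profile, ...)
  dl <- inflections$left$dose
  dr <- inflections$right$dose
  if (dl <= 0 || dr <= 0)
    stop("nonpositive inflection dose; profile is not a valid two-edged scan")
  if (combine == "mean") 2 * mean(c(dl, dr)) else c(left = 2 * dl, right = 2 * dr)
}

# single-side outermost crossing of `level`: for the left side the first
# upward crossing scanning inward from the left end, mirrored on the right
side_crossing <- function(x, d, level, side) {
  n <- length(x)
  idx <- if (side == "left") seq_len(n - 1) else rev(seq_len(n - 1))
  for (i in idx) {
    lo <- d[i] - level; hi <- d[i + 1] - level
    if (lo == 0) return(x[i])
    if (hi == 0) return(x[i + 1])
    if (lo * hi < 0)
      return(x[i] + (level - d[i]) * (x[i + 1] - x[i]) / (d[i + 1] - d[i]))
  }
  stop(sprintf("dose level %.4g is not crossed on the %s side", level, side))
}

#' Outermost crossings of a dose level
#'
#' Locates, by linear interpolation between the bracketing samples, the
#' outermost position on each side where the profile crosses `level`.
#'
#' @param profile A [beam_profile()].
#' @param level Dose level, strictly between the out-of-field dose and the
#'   profile maximum on both sides.
#' @return Named numeric `c(x_left = , x_right = )` in cm.
#' @export
level_crossings <- function(profile, level) {
  stopifnot(inherits(profile, "beam_profile"))
  x <- profile$positions; d <- profile$doses
  c(x_left = side_crossing(x, d, level, "left"),
    x_right = side_crossing(x, d, level, "right"))
}

#' Delineate the lateral regions of a profile
#'
#' Applies the four-region description: (1) field edges at 50% of the
#' reference dose, (2) penumbrae between the 20% and 80% points, (3) primary
#' region = central 80% of the field size, (4) out-of-field region beyond
#' 120% of the field size. In `"unflattened"` mode the reference dose comes
#' from [reference_dose()] (twice the inflection dose); in `"flattened"` mode
#' it is the conventional central-axis dose. Level crossings always use the
#' raw profile; smoothing applies only to inflection finding.
#'
#' The primary/out-of-field fractions are taken about the field centre (the
#' midpoint of the 50% edges), which is robust to mis-centred scans.
#'
#' @inheritParams find_inflections
#' @param mode `"unflattened"` or `"flattened"`.
#' @param combine Reference-dose combination, see [reference_dose()].
#' @return An object of class `profile_regions`: a list with
#'   `reference_dose`, `edge_left`, `edge_right`, `field_size`,
#'   `penumbra_left`, `penumbra_right`, `primary_interval`,
#'   `in_field_boundary` (distance, 0.6 x field size), `center`, `mode`, and
#'   `inflections` diagnostics (unflattened mode).
#' @examples
#' x <- seq(-9, 9, by = 0.1)
#' d <- pmax(0, 1 - 0.04 * abs(x)) /
#'   ((1 + exp((x - 5) / 0.3)) * (1 + exp(-(x + 5) / 0.3)))
#' classify_regions(beam_profile(x, 100 * d), mode = "unflattened")
#' @export
classify_regions <- function(profile, mode = c("unflattened", "flattened"),
                             smooth_window = 5, combine = c("mean", "per_side"),
                             tie = c("error", "first-from-center")) {
  stopifnot(inherits(profile, "beam_profile"))
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  tie <- match.arg(tie)
  x <- profile$positions; d <- profile$doses
  infl <- NULL
  if (mode == "unflattened") {
    infl <- find_inflections(profile, smooth_window = smooth_window, tie = tie)
    ref <- reference_dose(profile, infl, combine = combine)
  } else {
    ref <- interp_dose(x, d, 0)
    if (ref <= 0) stop("central-axis dose is nonpositive; cannot normalize flattened profile")
  }
  ref_side <- function(side) if (length(ref) == 2) ref[[side]] else ref
  lvl <- function(f, side) f * ref_side(side)
  edge_left <- side_crossing(x, d, lvl(0.5, "left"), "left")
  edge_right <- side_crossing(x, d, lvl(0.5, "right"), "right")
  if (edge_left >= edge_right) stop("invalid profile: left edge not left of right edge")
  fs <- edge_right - edge_left
  pen_left <- abs(side_crossing(x, d, lvl(0.8, "left"), "left") -
                  side_crossing(x, d, lvl(0.2, "left"), "left"))
  pen_right <- abs(side_crossing(x, d, lvl(0.8, "right"), "right") -
                   side_crossing(x, d, lvl(0.2, "right"), "right"))
  center <- (edge_left + edge_right) / 2
  structure(list(
    reference_dose = ref,
    edge_left = edge_left, edge_right = edge_right,
    field_size = fs,
    penumbra_left = pen_left, penumbra_right = pen_right,
    primary_interval = c(center - 0.4 * fs, center + 0.4 * fs),
    in_field_boundary = 0.6 * fs,
    center = center,
    mode = mode,
    inflections = infl), class = "profile_regions")
}

#' @export
print.profile_regions <- function(x, ...) {
  cat(sprintf("<profile_regions> (%s mode)\n", x$mode))
  cat(sprintf("  reference dose : %s\n", paste(format(x$reference_dose, digits = 5), collapse = " / ")))
  cat(sprintf("  field size     : %.3f cm  [%.3f, %.3f]\n", x$field_size, x$edge_left, x$edge_right))
  cat(sprintf("  penumbra L/R   : %.3f / %.3f cm\n", x$penumbra_left, x$penumbra_right))
  cat(sprintf("  primary region : [%.3f, %.3f] cm\n", x$primary_interval[1], x$primary_interval[2]))
  cat(sprintf("  out-of-field   : |x - %.3f| > %.3f cm\n", x$center, x$in_field_boundary))
  invisible(x)
}

#' Mean out-of-field dose as percent of the reference dose
#'
#' Averages the dose over all samples beyond 120% of the field size (i.e.
#' farther than 0.6 x field size from the field centre) and expresses it as
#' a percentage of the reference dose.
#'
#' @param profile A [beam_profile()].
#' @param regions A `profile_regions` result for `profile`; computed with
#'   default settings if missing.
#' @param ... Passed to [classify_regions()] when `regions` is missing.
#' @return Percent of the reference dose (scalar).
#' @export
out_of_field_dose <- function(profile, regions = NULL, ...) {
  stopifnot(inherits(profile, "beam_profile"))
  if (is.null(regions)) regions <- classify_regions(profile, ...)
  sel <- abs(profile$positions - regions$center) > regions$in_field_boundary
  if (!any(sel))
    stop("profile does not extend beyond the out-of-field boundary (",
         format(regions$in_field_boundary, digits = 4), " cm from centre)")
  ref <- if (length(regions$reference_dose) == 2)
    mean(regions$reference_dose) else regions$reference_dose
  100 * mean(profile$doses[sel]) / ref
}
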