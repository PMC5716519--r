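# Short-term (frame-wise) beam stability for static and gated delivery,
# and long-term daily-QA trending.
#
# At high dose rate a substantial dose is delivered before the linac servo
# reacts, so the first detector frame(s) after beam-on can differ from the
# settled profile; in gated delivery that ramp repeats at every beam-on
# cycle, with a period set by the gating window.

# mean profile over beam-on frames
series_reference <- function(series) {
  on <- if (is.null(series$beam_on)) rep(TRUE, nrow(series$frames)) else series$beam_on
  if (!any(on)) stop("no beam-on frames")
  colMeans(series$frames[on, , drop = FALSE])
}

normalize_cax <- function(x, positions) {
  cax <- stats::approx(positions, x, xout = 0)$y
  if (!is.finite(cax) || cax <= 0) stop("central-axis value nonpositive; cannot normalize frame")
  x / cax
}

#' Per-frame, per-point percent difference from a reference profile
#'
#' Each frame and the reference are first normalized to their own
#' central-axis value, so that shape instability is measured rather than
#' output ramp-up; the result is `100 * (frame - reference) / reference`
#' per detector point. Points where the reference falls below 5% of its
#' maximum are flagged unreliable (attribute `unreliable`) — relative
#' differences there are dominated by noise.
#'
#' @param series A [frame_series()] with >= 2 frames.
#' @param reference Reference profile over `series$positions`; defaults to
#'   the mean over beam-on frames.
#' @return Matrix (frame x position) of percent differences, with logical
#'   attribute `unreliable` (per position).
#' @export
frame_percent_diff <- function(series, reference = NULL) {
  stopifnot(inherits(series, "frame_series"))
  if (nrow(series$frames) < 2) stop("need at least 2 frames")
  if (is.null(reference)) reference <- series_reference(series)
  if (length(reference) != length(series$positions))
    stop("reference must match the detector positions")
  ref <- normalize_cax(reference, series$positions)
  unreliable <- ref < 0.05 * max(ref)
  if (any(ref == 0 & !unreliable)) stop("zero reference dose at an unflagged point")
  fr <- t(apply(series$frames, 1, normalize_cax, positions = series$positions))
  pd <- 100 * sweep(sweep(fr, 2, ref, "-"), 2, ref, "/")
  structure(pd, unreliable = unreliable)
}

# logical position mask of points excluded from stability judgements:
# penumbra intervals of the reference profile plus unreliable (low-dose)
# points
stability_exclusion <- function(series, reference, unreliable) {
  p <- beam_profile(series$positions, pmax(reference, 0))
  regions <- classify_regions(p, mode = "unflattened",
                              tie = "first-from-center")
  x <- series$positions
  pen <- function(side) {
    ref <- if (length(regions$reference_dose) == 2)
      regions$reference_dose[[side]] else regions$reference_dose
    sort(c(side_crossing(p$positions, p$doses, 0.2 * ref, side),
           side_crossing(p$positions, p$doses, 0.8 * ref, side)))
  }
  # pad by one detector spacing so edge-adjacent samples are excluded even
  # when the 20-80% interval falls between two coarse detector positions
  pad <- stats::median(diff(x))
  pl <- pen("left"); pr <- pen("right")
  in_pen <- (x >= pl[1] - pad & x <= pl[2] + pad) |
            (x >= pr[1] - pad & x <= pr[2] + pad)
  in_pen | unreliable
}

#' Number of unstable leading frames
#'
#' Finds the smallest frame index k such that every frame from k on has all
#' non-excluded points within `tol` percent of the reference profile, and
#' returns `k - 1` — the number of unstable leading frames. Points in the
#' penumbra of the average profile (where tiny positional jitter produces
#' large relative differences) and unreliable low-dose points are excluded.
#'
#' @param series A [frame_series()].
#' @param tol Tolerance in percent (default 2).
#' @param exclude `"penumbra"` (default) to exclude penumbra and low-dose
#'   points, `"none"` to judge every point.
#' @return Integer count of unstable leading frames, with attribute
#'   `stable` (`FALSE` when the series never settles, in which case the
#'   frame count is returned).
#' @export
ramp_up_length <- function(series, tol = 2, exclude = c("penumbra", "none")) {
  exclude <- match.arg(exclude)
  reference <- series_reference(series)
  pd <- frame_percent_diff(series, reference)
  excl <- if (exclude == "penumbra")
    stability_exclusion(series, reference, attr(pd, "unreliable"))
  else attr(pd, "unreliable")
  use <- !excl
  if (!any(use)) stop("all points excluded; cannot judge stability")
  frame_ok <- apply(abs(pd[, use, drop = FALSE]) <= tol, 1, all)
  n <- length(frame_ok)
  # last frame violating tol; everything after it is the stable suffix
  bad <- which(!frame_ok)
  if (length(bad) == 0) return(structure(0L, stable = TRUE))
  if (bad[length(bad)] == n) return(structure(n, stable = FALSE))
  structure(as.integer(bad[length(bad)]), stable = TRUE)
}

#' Ramp-pattern repetition period in a gated frame series
#'
#' In gated delivery every beam-on cycle starts with ramp frames that differ
#' from the settled profile. Ramp frames are detected as frames whose
#' maximum absolute percent difference (over non-excluded points) exceeds
#' `tol`; the period is the median gap, in frames, between successive ramp
#' onsets. When the series carries a `gate_window`, the analytic expectation
#' `gate_window / frame_period` is reported alongside.
#'
#' @param series A gated [frame_series()].
#' @param tol Ramp-detection tolerance in percent (default 2).
#' @return List with `period_frames` (median onset gap), `onsets` (frame
#'   indices), and `expected_frames` (`gate_window / frame_period`, `NA` if
#'   no gate window is recorded).
#' @export
gating_cycle_period <- function(series, tol = 2) {
  reference <- series_reference(series)
  pd <- frame_percent_diff(series, reference)
  excl <- stability_exclusion(series, reference, attr(pd, "unreliable"))
  use <- !excl
  ramp <- apply(abs(pd[, use, drop = FALSE]) > tol, 1, any)
  onsets <- which(ramp & !c(FALSE, ramp[-length(ramp)]))
  if (length(onsets) < 2)
    stop("fewer than 2 ramp onsets detected; cannot estimate a period")
  list(period_frames = stats::median(diff(onsets)),
       onsets = onsets,
       expected_frames = if (!is.null(series$gate_window))
         series$gate_window / series$frame_period else NA_real_)
}

#' Daily-QA trend summary
#'
#' For each recorded metric (output offset and, when present, cross-plane /
#' in-plane symmetry offsets): number of records, mean, standard deviation
#' (n - 1 denominator), tolerance exceedances (strictly `|offset| >
#' tolerance`: a reading exactly at tolerance passes) with their dates, and
#' a differential histogram at the stated bin width.
#'
#' @param series A [qa_series()] with >= 2 records.
#' @param bin_width Histogram bin width in percent (default 0.5).
#' @return List of per-metric summaries, each with `n`, `mean`, `sd`,
#'   `n_exceed`, `exceed_dates`, `histogram` (data frame `lower`, `upper`,
#'   `count`), plus `tolerance` at the top level.
#' @export
qa_trend <- function(series, bin_width = 0.5) {
  stopifnot(inherits(series, "qa_series"))
  if (length(series$dates) < 2) stop("need at least 2 QA records")
  tol <- series$tolerance
  one <- function(v) {
    if (is.null(v)) return(NULL)
    exceed <- abs(v) > tol
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE,
                        include.lowest = TRUE)
    list(n = length(v), mean = mean(v), sd = stats::sd(v),
         n_exceed = sum(exceed), exceed_dates = series$dates[exceed],
         histogram = data.frame(lower = utils::head(h$breaks, -1),
                                upper = h$breaks[-1], count = h$counts))
  }
  out <- list(output_offset = one(series$output_offset),
              sym_cp = one(series$sym_cp), sym_ip = one(series$sym_ip))
  out <- out[!vapply(out, is.null, logical(1))]
  out$tolerance <- tol
  out
}

#' Compare the variability of two QA series
#'
#' Two-sided F test on the variance ratio of the output offsets (the test
#' choice is recorded in the result; it is a default, not the only sensible
#' option for this comparison).
#'
#' @param series_a,series_b [qa_series()] objects with >= 2 records each.
#' @return List with `p_value`, `statistic` (F), `df`, `method`.
#' @export
compare_variability <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "qa_series"), inherits(series_b, "qa_series"))
  a <- series_a$output_offset; b <- series_b$output_offset
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 records per series")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate series: zero variance")
  ft <- stats::var.test(a, b)
  list(p_value = unname(ft$p.value), statistic = unname(ft$statistic),
       df = unname(ft$parameter), method = "two-sided F test on variance ratio")
}
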