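#' Cross-axis beam profile
#'
#' Container for a single lateral dose scan at a stated depth. Positions are
#' off-axis distances in cm at the measurement depth with the field centre
#' near 0; doses are relative (arbitrary units or percent).
#'
#' @param positions Numeric vector of off-axis positions in cm, strictly
#'   increasing.
#' @param doses Numeric vector of nonnegative dose values, same length as
#'   `positions` (at least 5 points).
#' @param depth Measurement depth in cm (>= 0), `NA` if unknown.
#' @param ssd Source-to-surface distance in cm (default 100).
#' @param field_nominal Nominal square field side in cm, `NA` if unknown.
#' @param label Free-text label, e.g. `"WF"` or `"eqUF"`.
#' @return An object of class `beam_profile`.
#' @examples
#' x <- seq(-8, 8, by = 0.2)
#' d <- 100 / (1 + exp((abs(x) - 5) / 0.3))
#' p <- beam_profile(x, d, depth = 10)
#' @export
beam_profile <- function(positions, doses, depth = NA_real_, ssd = 100,
                         field_nominal = NA_real_, label = "") {
  positions <- as.numeric(positions)
  doses <- as.numeric(doses)
  if (length(positions) != length(doses))
    stop("positions and doses must have equal length")
  if (length(positions) < 5)
    stop("a beam profile needs at least 5 samples, got ", length(positions))
  if (anyNA(positions) || anyNA(doses))
    stop("positions and doses must not contain NA")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(doses < 0))
    stop("doses must be nonnegative")
  if (!is.na(depth) && depth < 0)
    stop("depth must be >= 0")
  structure(
    list(positions = positions, doses = doses, depth = depth, ssd = ssd,
         field_nominal = field_nominal, label = as.character(label)),
    class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("<beam_profile> %d points, x in [%.3g, %.3g] cm", length(x$positions),
              min(x$positions), max(x$positions)))
  if (!is.na(x$depth)) cat(sprintf(", depth %.3g cm", x$depth))
  if (nzchar(x$label)) cat(sprintf(", label '%s'", x$label))
  cat("\n")
  invisible(x)
}

#' Central-axis depth-dose curve
#'
#' @param depths Numeric vector of depths in cm, strictly increasing, >= 0.
#' @param doses Numeric vector of nonnegative doses.
#' @param normalized Logical; `TRUE` when the curve has been scaled so its
#'   maximum equals 100 (percent depth dose).
#' @return An object of class `depth_dose_curve`.
#' @seealso [normalize_pdd()], [find_dmax()], [pdd_at()]
#' @export
depth_dose_curve <- function(depths, doses, normalized = FALSE) {
  depths <- as.numeric(depths)
  doses <- as.numeric(doses)
  if (length(depths) != length(doses))
    stop("depths and doses must have equal length")
  if (anyNA(depths) || anyNA(doses))
    stop("depths and doses must not contain NA")
  if (any(depths < 0))
    stop("depths must be >= 0")
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing")
  if (any(doses < 0))
    stop("doses must be nonnegative")
  if (normalized && abs(max(doses) - 100) > 1e-6)
    stop("normalized curve must have max dose 100")
  structure(list(depths = depths, doses = doses, normalized = isTRUE(normalized)),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d points, depth in [%.3g, %.3g] cm%s\n",
              length(x$depths), min(x$depths), max(x$depths),
              if (x$normalized) ", normalized (%dd)" else ""))
  invisible(x)
}

#' Time-resolved detector-array frame series
#'
#' Frames from a linear detector array acquiring one lateral profile per
#' readout frame (0.072 s per frame by default). For gated delivery, frames
#' are the ones recorded while the beam is on; `gate_window` records the
#' beam-on window length used.
#'
#' @param frames Numeric matrix, one row per frame, one column per detector
#'   position; all doses >= 0.
#' @param positions Detector positions in cm (default 0.5 cm spacing grid
#'   matching `ncol(frames)` is required).
#' @param frame_period Frame period in seconds (default 0.072).
#' @param beam_on Optional logical vector, one flag per frame.
#' @param gate_window Optional beam-on window length in seconds for gated
#'   delivery.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, positions, frame_period = 0.072,
                         beam_on = NULL, gate_window = NULL) {
  frames <- as.matrix(frames)
  positions <- as.numeric(positions)
  if (frame_period <= 0) stop("frame_period must be > 0")
  if (ncol(frames) != length(positions))
    stop("each frame must have one dose per position")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(frames < 0)) stop("doses must be nonnegative")
  if (!is.null(beam_on)) {
    beam_on <- as.logical(beam_on)
    if (length(beam_on) != nrow(frames))
      stop("beam_on needs one flag per frame")
  }
  structure(list(frames = frames, positions = positions,
                 frame_period = frame_period, beam_on = beam_on,
                 gate_window = gate_window),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames x %d positions, %.3f s/frame%s\n",
              nrow(x$frames), length(x$positions), x$frame_period,
              if (!is.null(x$gate_window)) sprintf(", gated (%.3g s window)", x$gate_window) else ""))
  invisible(x)
}

#' Daily-QA record series
#'
#' Output-constancy and symmetry offsets from daily machine QA, in percent,
#' with the tolerance used to judge them (3% by default).
#'
#' @param dates Vector coercible to `Date`, nondecreasing.
#' @param output_offset Output offsets in percent.
#' @param sym_cp,sym_ip Optional cross-plane / in-plane symmetry offsets in
#'   percent.
#' @param tolerance Tolerance in percent (> 0, default 3).
#' @return An object of class `qa_series`.
#' @export
qa_series <- function(dates, output_offset, sym_cp = NULL, sym_ip = NULL,
                      tolerance = 3) {
  dates <- as.Date(dates)
  output_offset <- as.numeric(output_offset)
  if (length(dates) != length(output_offset))
    stop("dates and output_offset must have equal length")
  if (anyNA(dates)) stop("dates must parse as Date")
  if (is.unsorted(dates)) stop("dates must be nondecreasing")
  if (tolerance <= 0) stop("tolerance must be > 0")
  for (s in list(sym_cp, sym_ip))
    if (!is.null(s) && length(s) != length(dates))
      stop("symmetry columns must match the number of dates")
  structure(list(dates = dates, output_offset = output_offset,
                 sym_cp = sym_cp, sym_ip = sym_ip, tolerance = tolerance),
            class = "qa_series")
}

#' @export
print.qa_series <- function(x, ...) {
  cat(sprintf("<qa_series> %d records, %s .. %s, tolerance %.3g%%\n",
              length(x$dates), min(x$dates), max(x$dates), x$tolerance))
  invisible(x)
}

# linear interpolation of a profile/PDD dose at x; errors outside the range
interp_dose <- function(xs, ds, x, what = "position") {
  if (any(x < min(xs) - 1e-12) || any(x > max(xs) + 1e-12))
    stop("requested ", what, " outside the sampled range [",
         format(min(xs)), ", ", format(max(xs)), "]")
  stats::approx(xs, ds, xout = pmin(pmax(x, min(xs)), max(xs)), rule = 1)$y
}
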