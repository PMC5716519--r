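# Scatter-factor bookkeeping and off-axis-ratio depth-variation analysis.
#
# Sc (in-air collimator/head scatter) and Scp (total scatter in water) are
# measured per square field size; the phantom scatter factor is recovered as
# Sp = Scp / Sc, and all three are normalized to 1 at the reference field
# (10 x 10 cm2 by default).

#' Build a scatter-factor table
#'
#' @param field_sizes Square field side lengths in cm.
#' @param sc In-air collimator scatter factors (> 0).
#' @param scp Total scatter factors in water (> 0).
#' @param norm_field Reference field size present in `field_sizes`
#'   (default 10).
#' @return An object of class `scatter_table`: a data frame with columns
#'   `field_cm`, `sc`, `scp`, `sp`, each factor column normalized to 1 at
#'   `norm_field`, with attribute `norm_field`.
#' @examples
#' phantom_scatter(c(3, 10, 40), sc = c(0.96, 1, 1.04), scp = c(0.93, 1, 1.08))
#' @export
phantom_scatter <- function(field_sizes, sc, scp, norm_field = 10) {
  field_sizes <- as.numeric(field_sizes)
  sc <- as.numeric(sc); scp <- as.numeric(scp)
  if (length(field_sizes) != length(sc) || length(sc) != length(scp))
    stop("field_sizes, sc and scp must have equal length")
  if (any(sc <= 0) || any(scp <= 0))
    stop("scatter factors must be > 0")
  i0 <- which(abs(field_sizes - norm_field) < 1e-9)
  if (length(i0) != 1)
    stop("norm_field ", norm_field, " must appear exactly once in field_sizes")
  sc_n <- sc / sc[i0]
  scp_n <- scp / scp[i0]
  sp_n <- scp_n / sc_n
  out <- data.frame(field_cm = field_sizes, sc = sc_n, scp = scp_n, sp = sp_n)
  out <- out[order(out$field_cm), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, norm_field = norm_field,
            class = c("scatter_table", "data.frame"))
}

#' Range of a factor or %dd column across field sizes
#'
#' Variation is defined as the range (max - min). For factors normalized to
#' 1 at the reference field the range is reported in percent of the
#' reference value (x 100); for %dd values it is already in percentage
#' points and reported as-is.
#'
#' @param values Numeric vector of values by field size (>= 2 entries).
#' @param scale `"factor"` (multiply the range by 100) or `"percent"`
#'   (values already in percentage points).
#' @return Variation in percent.
#' @export
variation_across_fields <- function(values, scale = c("factor", "percent")) {
  scale <- match.arg(scale)
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need values for at least 2 field sizes")
  r <- max(values) - min(values)
  if (scale == "factor") 100 * r else r
}

#' Relative reduction between two variations
#'
#' `(var_a - var_b) / var_a * 100`: how much smaller (in percent of `var_a`)
#' the second beam's variation is than the first's.
#'
#' @param var_a Baseline variation in percent (> 0).
#' @param var_b Comparison variation in percent.
#' @return Relative reduction in percent.
#' @examples
#' relative_reduction(9.5, 7.5)  # ~21.1% less variation
#' @export
relative_reduction <- function(var_a, var_b) {
  if (var_a <= 0) stop("baseline variation must be > 0")
  (var_a - var_b) / var_a * 100
}

#' Remove beam divergence from a profile
#'
#' Projects the off-axis positions from the measurement depth onto a common
#' reference depth assuming a point source at `ssd + depth` from the
#' measurement plane (fixed-SSD water-tank setup): positions are scaled by
#' `(ssd + ref_depth) / (ssd + depth)`, doses are unchanged, and the depth
#' metadata is updated to `ref_depth`. Comparing profiles projected this way
#' isolates off-axis spectral softening from pure geometric divergence.
#'
#' @param profile A [beam_profile()] with `ssd` and `depth` set.
#' @param ref_depth Reference depth in cm.
#' @return A [beam_profile()] at `ref_depth` with scaled positions.
#' @export
remove_divergence <- function(profile, ref_depth) {
  stopifnot(inherits(profile, "beam_profile"))
  if (is.na(profile$depth) || is.na(profile$ssd))
    stop("profile needs depth and ssd metadata to remove divergence")
  f <- (profile$ssd + ref_depth) / (profile$ssd + profile$depth)
  beam_profile(profile$positions * f, profile$doses, depth = ref_depth,
               ssd = profile$ssd, field_nominal = profile$field_nominal,
               label = paste0(profile$label,
                              sprintf(" [divergence removed: %.4g -> %.4g cm]",
                                      profile$depth, ref_depth)))
}

# off-axis ratio at off_axis for one profile: normalize to the central-axis
# dose first (OAR is defined per depth), then optionally project positions
oar_at <- function(profile, off_axis, ref_depth, divergence) {
  cax <- interp_dose(profile$positions, profile$doses, 0)
  if (cax <= 0) stop("central-axis dose is nonpositive")
  p <- beam_profile(profile$positions, profile$doses / cax,
                    depth = profile$depth, ssd = profile$ssd,
                    field_nominal = profile$field_nominal, label = profile$label)
  if (divergence == "remove") p <- remove_divergence(p, ref_depth)
  interp_dose(p$positions, p$doses, off_axis)
}

#' Off-axis-ratio variation across depths
#'
#' For a set of profiles of one beam measured at several depths, computes
#' the off-axis ratio OAR(x, d) = D(x, d) / D(0, d) at a fixed off-axis
#' distance and reports its variation (range, max - min) over depth,
#' optionally with beam divergence removed so that only off-axis softening
#' remains. When a second beam's profiles are supplied, the ratio of the
#' two variations is reported as well.
#'
#' @param profiles List of [beam_profile()]s of one beam, one per depth
#'   (>= 2 depths).
#' @param off_axis Off-axis distance in cm at which OAR is evaluated.
#' @param ref_depth Reference depth in cm for divergence removal.
#' @param divergence `"keep"` or `"remove"`.
#' @param profiles_b Optional list of profiles of a second beam.
#' @return List with `oar` (named by depth), `variation` (percent range of
#'   OAR, i.e. range x 100); when `profiles_b` is given also `variation_b`
#'   and `ratio` (= variation / variation_b).
#' @export
oar_depth_variation <- function(profiles, off_axis, ref_depth = NULL,
                                divergence = c("keep", "remove"),
                                profiles_b = NULL) {
  divergence <- match.arg(divergence)
  if (divergence == "remove" && is.null(ref_depth))
    stop("ref_depth is required when removing divergence")
  one_beam <- function(ps) {
    if (length(ps) < 2) stop("need profiles at >= 2 depths")
    oar <- vapply(ps, oar_at, numeric(1), off_axis = off_axis,
                  ref_depth = ref_depth, divergence = divergence)
    names(oar) <- vapply(ps, function(p) format(p$depth), character(1))
    list(oar = oar, variation = 100 * (max(oar) - min(oar)))
  }
  a <- one_beam(profiles)
  out <- list(oar = a$oar, variation = a$variation)
  if (!is.null(profiles_b)) {
    b <- one_beam(profiles_b)
    out$oar_b <- b$oar
    out$variation_b <- b$variation
    if (b$variation <= 0) stop("second beam has zero OAR variation; ratio undefined")
    out$ratio <- a$variation / b$variation
  }
  out
}
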