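# Seeded synthetic beam-data generator.
#
# Profiles are built as [cone or flat-with-horns factor] x [logistic edge at
# +FS/2] x [logistic edge at -FS/2] + tail. Logistic (rather than
# error-function) edges are used so the penumbra and inflection dose have
# closed forms: a logistic edge of scale w has its inflection at the edge
# centre at half the local plateau, and an 80-20 distance of 2*ln(4)*w.
# Depth-dose curves use the minimal buildup-attenuation model
# D(z) = (1 - exp(-a z)) * exp(-mu z), whose two parameters are exactly
# identified by a (dmax, %dd(10)) target pair.

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Synthetic beam specification
#'
#' Bundles the shape and depth-dose parameters of one synthetic beam. The
#' depth-dose targets default to the matched-beam convention for a 6 MV
#' beam line: flattened beam (dmax 1.5 cm, %dd(10) 67.1), energy-unaltered
#' unflattened beam (1.3 cm, 63.8), and quality-matched unflattened beam
#' (1.8 cm, 67.0). The unflattened edge is slightly wider and its
#' out-of-field tail lower than the flattened beam's.
#'
#' @param beam_type `"flattened"` or `"unflattened"`.
#' @param field_size Nominal square field side in cm (default 10).
#' @param edge_width Logistic edge scale in cm (default 0.25 flattened /
#'   0.30 unflattened).
#' @param cone_slope Fractional dose fall-off per cm off-axis for
#'   unflattened beams (default 0.04).
#' @param horn_amplitude Fractional horn height near the field edge,
#'   flattened beams only (default 0.02).
#' @param tail_level Out-of-field tail as a fraction of the reference dose
#'   (default 0.03 flattened / 0.015 unflattened; must be < 0.5).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   peak dose (default 0).
#' @param seed Integer seed for all randomness drawn from this spec.
#' @param ssd Source-to-surface distance in cm (default 100).
#' @param pdd_targets Numeric `c(dmax = , pdd10 = )` pair; defaults by
#'   `beam_type` as above (`"unflattened"` uses the quality-matched
#'   targets).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(beam_type = c("unflattened", "flattened"),
                      field_size = 10, edge_width = NULL, cone_slope = 0.04,
                      horn_amplitude = 0.02, tail_level = NULL, noise_sd = 0,
                      seed = 1L, ssd = 100, pdd_targets = NULL) {
  beam_type <- match.arg(beam_type)
  uf <- beam_type == "unflattened"
  edge_width <- edge_width %||% if (uf) 0.30 else 0.25
  tail_level <- tail_level %||% if (uf) 0.015 else 0.03
  pdd_targets <- pdd_targets %||%
    if (uf) c(dmax = 1.8, pdd10 = 67.0) else c(dmax = 1.5, pdd10 = 67.1)
  if (field_size <= 0) stop("field_size must be > 0")
  if (edge_width <= 0) stop("edge_width must be > 0")
  if (tail_level < 0 || tail_level >= 0.5) stop("tail_level must be in [0, 0.5)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(beam_type = beam_type, field_size = field_size,
                 edge_width = edge_width, cone_slope = cone_slope,
                 horn_amplitude = horn_amplitude, tail_level = tail_level,
                 noise_sd = noise_sd, seed = as.integer(seed), ssd = ssd,
                 pdd_targets = pdd_targets),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %s, %g x %g cm, edge %g cm, tail %g, noise %g, seed %d\n",
              x$beam_type, x$field_size, x$field_size, x$edge_width,
              x$tail_level, x$noise_sd, x$seed))
  invisible(x)
}

# noiseless profile shape on a position grid, peak ~1.
#
# Multiplying a logistic edge sigma((e - x)/w) by a lateral factor g(x)
# shifts the product's inflection: at the inflection sigma* = 1/2 - w g'/g.
# The edge centres are therefore offset so the inflection (and with it the
# 50%-of-reference crossing) lands exactly at +/- field_size/2 for
# noiseless output.
profile_shape <- function(spec, x) {
  fs2 <- spec$field_size / 2
  w <- spec$edge_width
  if (spec$beam_type == "unflattened") {
    g_edge <- 1 - spec$cone_slope * fs2
    if (g_edge <= 0)
      stop("cone_slope * field_size/2 >= 1: no dose left at the field edge")
    rho <- -spec$cone_slope / g_edge        # g'/g at the right edge
  } else {
    g_edge <- 1 + spec$horn_amplitude
    rho <- 2 * spec$horn_amplitude / fs2 / g_edge
  }
  sigma_star <- 0.5 - w * rho
  if (sigma_star <= 0 || sigma_star >= 1)
    stop("edge_width too large for the lateral slope at the field edge")
  e <- fs2 - w * log((1 - sigma_star) / sigma_star)
  edges <- 1 / ((1 + exp((x - e) / w)) * (1 + exp(-(x + e) / w)))
  shape <- if (spec$beam_type == "unflattened") {
    pmax(0, 1 - spec$cone_slope * abs(x))
  } else {
    1 + spec$horn_amplitude * pmin(1, abs(x) / fs2)^2
  }
  # local plateau at the edge sets the reference scale for the tail
  shape * edges + spec$tail_level * g_edge
}

#' Generate a synthetic cross-axis profile
#'
#' Construction places the 50%-of-reference crossings at +/- field_size/2
#' for noiseless output (the logistic edge's inflection is at the edge
#' centre at half the local plateau). Gaussian noise of `spec$noise_sd`
#' times the peak is added per point, seeded from `spec$seed`.
#'
#' @param spec A [beam_spec()].
#' @param depth Measurement depth in cm (default 10).
#' @param grid_step Sampling step in cm (default 0.1, i.e. 1 mm).
#' @param span Half-width of the scan in cm; defaults to
#'   `0.6 * field_size + 5` so the out-of-field region is covered.
#' @return A [beam_profile()] with doses scaled to 100 at the (noiseless)
#'   peak.
#' @export
make_profile <- function(spec, depth = 10, grid_step = 0.1, span = NULL) {
  stopifnot(inherits(spec, "beam_spec"))
  if (grid_step >= spec$edge_width)
    warning("grid_step >= edge_width: the penumbra is undersampled")
  span <- span %||% (0.6 * spec$field_size + 5)
  x <- seq(-span, span, by = grid_step)
  s <- profile_shape(spec, x)
  d <- 100 * s / max(s)
  if (spec$noise_sd > 0)
    d <- d + with_seed(spec$seed, stats::rnorm(length(x), 0, spec$noise_sd * max(d)))
  beam_profile(x, pmax(d, 0), depth = depth, ssd = spec$ssd,
               field_nominal = spec$field_size,
               label = if (spec$beam_type == "unflattened") "UF" else "WF")
}

# dmax of the buildup-attenuation model, closed form
model_dmax <- function(a, mu) log((a + mu) / mu) / a

# %dd(10) of the model, closed form
model_pdd10 <- function(a, mu) {
  z <- model_dmax(a, mu)
  f <- function(zz) (1 - exp(-a * zz)) * exp(-mu * zz)
  100 * f(10) / f(z)
}

# solve (a, mu) so the model hits (dmax, pdd10); nested root finds
solve_pdd_params <- function(dmax, pdd10) {
  a_for_mu <- function(mu) {
    g <- function(a) model_dmax(a, mu) - dmax
    lo <- 1e-3; hi <- 50
    if (g(lo) < 0 || g(hi) > 0) return(NA_real_)
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  h <- function(mu) {
    a <- a_for_mu(mu)
    if (is.na(a)) return(NA_real_)
    model_pdd10(a, mu) - pdd10
  }
  mus <- c(1e-4, 0.2)
  hv <- vapply(mus, h, numeric(1))
  if (anyNA(hv) || prod(sign(hv)) > 0)
    stop(sprintf(paste0("depth-dose targets (dmax = %.3g cm, pdd10 = %.3g) are ",
                        "infeasible for the buildup-attenuation model within ",
                        "mu in [%.4g, %.4g], a in [0.001, 50]"),
                 dmax, pdd10, mus[1], mus[2]))
  mu <- stats::uniroot(h, mus, tol = 1e-12)$root
  c(a = a_for_mu(mu), mu = mu)
}

#' Generate a synthetic depth-dose curve
#'
#' Solves the buildup-attenuation model
#' `D(z) = (1 - exp(-a z)) * exp(-mu z)` for the parameter pair hitting the
#' spec's `(dmax, pdd10)` targets, samples it on a regular depth grid and
#' returns the normalized curve.
#'
#' @param spec A [beam_spec()] with `pdd_targets` set.
#' @param grid_step Depth sampling step in cm (default 0.05).
#' @param max_depth Deepest sample in cm (default 30).
#' @return A normalized [depth_dose_curve()] with attribute `model_params`
#'   (`a`, `mu`).
#' @export
make_pdd <- function(spec, grid_step = 0.05, max_depth = 30) {
  stopifnot(inherits(spec, "beam_spec"))
  t <- spec$pdd_targets
  par <- solve_pdd_params(t[["dmax"]], t[["pdd10"]])
  z <- seq(0, max_depth, by = grid_step)
  d <- (1 - exp(-par[["a"]] * z)) * exp(-par[["mu"]] * z)
  out <- normalize_pdd(depth_dose_curve(z, d))
  attr(out, "model_params") <- par
  out
}

#' Generate a synthetic detector-array frame series
#'
#' Emulates a linear diode array reading one lateral profile per frame
#' (0.072 s default) on a 0.5 cm grid. The first `ramp_frames` frames of
#' each beam-on cycle are tilted linearly across the field by `ramp_tilt`
#' percent (the beam-steering transient before the servo settles); all
#' frames get multiplicative Gaussian noise of relative standard deviation
#' `spec$noise_sd`. For gated delivery only beam-on frames are recorded,
#' `ceiling(gate_window / frame_period)` per cycle.
#'
#' @param spec A [beam_spec()].
#' @param n_frames Number of recorded frames (>= 2).
#' @param gate_window Beam-on window in seconds, or `NULL` for static
#'   delivery; must be >= `frame_period`.
#' @param ramp_frames Number of unstable frames at each beam-on (default 1).
#' @param ramp_tilt Tilt of the unstable frames in percent at the field edge
#'   (default 5).
#' @param frame_period Frame period in seconds (default 0.072).
#' @param depth Measurement depth in cm for the base profile (default 10).
#' @return A [frame_series()].
#' @export
make_frames <- function(spec, n_frames, gate_window = NULL, ramp_frames = 1,
                        ramp_tilt = 5, frame_period = 0.072, depth = 10) {
  stopifnot(inherits(spec, "beam_spec"))
  if (n_frames < 2) stop("need n_frames >= 2")
  if (!is.null(gate_window) && gate_window < frame_period)
    stop("gate_window must be at least one frame period")
  base <- suppressWarnings(make_profile(
    beam_spec(spec$beam_type, field_size = spec$field_size,
              edge_width = spec$edge_width, cone_slope = spec$cone_slope,
              horn_amplitude = spec$horn_amplitude, tail_level = spec$tail_level,
              noise_sd = 0, seed = spec$seed, ssd = spec$ssd),
    depth = depth, grid_step = 0.5))
  x <- base$positions
  tilt_factor <- 1 + ramp_tilt / 100 * x / (spec$field_size / 2)
  per_cycle <- if (is.null(gate_window)) n_frames
               else as.integer(ceiling(gate_window / frame_period))
  in_cycle <- ((seq_len(n_frames) - 1L) %% per_cycle) + 1L
  is_ramp <- in_cycle <= ramp_frames
  frames <- with_seed(spec$seed, {
    t(vapply(seq_len(n_frames), function(i) {
      d <- base$doses * (if (is_ramp[i]) tilt_factor else 1)
      if (spec$noise_sd > 0)
        d <- d * (1 + stats::rnorm(length(x), 0, spec$noise_sd))
      pmax(d, 0)
    }, numeric(length(x))))
  })
  frame_series(frames, x, frame_period = frame_period,
               beam_on = rep(TRUE, n_frames), gate_window = gate_window)
}

#' Generate a synthetic daily-QA log
#'
#' Seeded Gaussian output offsets, dated daily.
#'
#' @param mean Mean offset in percent (default 0.60).
#' @param sd Standard deviation in percent (default 0.99).
#' @param n Number of daily records (default 1354).
#' @param seed Integer seed.
#' @param start Start date (default `"2005-01-01"`).
#' @param tolerance QA tolerance in percent (default 3).
#' @return A [qa_series()].
#' @export
make_qa_series <- function(mean = 0.60, sd = 0.99, n = 1354, seed = 1L,
                           start = "2005-01-01", tolerance = 3) {
  if (n < 2) stop("need n >= 2")
  if (sd < 0) stop("sd must be >= 0")
  offsets <- with_seed(seed, stats::rnorm(n, mean, sd))
  qa_series(seq(as.Date(start), by = "day", length.out = n), offsets,
            tolerance = tolerance)
}
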