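test_that("inflection of a logistic edge sits at the edge centre at half height", {
  p <- flat_top(e = 5, w = 0.25, step = 0.05)
  infl <- find_inflections(p)
  expect_equal(infl$right$position, 5, tolerance = 0.025 / 5)
  expect_equal(infl$right$dose, 50, tolerance = 0.5 / 50)
  expect_equal(infl$left$position, -5, tolerance = 0.025 / 5)
  expect_gt(infl$right$slope_magnitude, 0)
})

test_that("inflection positions of a symmetric profile are symmetric", {
  p <- make_profile(beam_spec("unflattened", field_size = 10), grid_step = 0.1)
  infl <- find_inflections(p)
  expect_lt(abs(infl$left$position + infl$right$position), 0.1)
})

test_that("coarse-grid inflections agree with a fine-grid second-derivative oracle", {
  # oracle: sign change of the numerical second derivative at 0.001 cm
  fs <- 10; w <- 0.3; slope <- 0.04
  shape <- function(x) pmax(0, 1 - slope * abs(x)) /
    ((1 + exp((x - fs / 2) / w)) * (1 + exp(-(x + fs / 2) / w)))
  xf <- seq(4, 6, by = 1e-3)
  d2 <- diff(diff(shape(xf)))
  j <- which(d2[-1] * d2[-length(d2)] < 0)[1]
  oracle_x <- xf[j + 1]

  p <- cone_profile(fs = fs, w = w, slope = slope, step = 0.2)
  infl <- find_inflections(p)
  expect_lt(abs(infl$right$position - oracle_x), 0.05)
})

test_that("monotone profiles are rejected and exact slope ties are surfaced", {
  expect_error(find_inflections(beam_profile(1:10, 1:10)), "no rising and falling edge")
  expect_error(find_inflections(beam_profile(1:10, rep(2, 10))), "no rising and falling edge")
  # linear edges have constant |slope|: every edge sample ties
  tri <- beam_profile(-3:3, c(0, 1, 2, 3, 2, 1, 0))
  expect_error(find_inflections(tri, smooth_window = 1), "tie")
  infl <- find_inflections(tri, smooth_window = 1, tie = "first-from-center")
  expect_lt(abs(infl$right$position), 3)
})

test_that("reference dose doubles the inflection dose, mean or per side", {
  fake <- list(left = list(dose = 40), right = list(dose = 44))
  expect_equal(reference_dose(NULL, fake), 84)
  expect_equal(reference_dose(NULL, fake, combine = "per_side"),
               c(left = 80, right = 88))
  expect_equal(reference_dose(NULL, list(left = list(dose = 50),
                                         right = list(dose = 50))), 100)
  expect_error(reference_dose(NULL, list(left = list(dose = 0),
                                         right = list(dose = 50))),
               "nonpositive")
})

test_that("for a flat-top profile the reference dose equals the plateau", {
  p <- flat_top(e = 5, w = 0.25, top = 100)
  ref <- reference_dose(p)
  expect_equal(ref, 100, tolerance = 0.01)
})

test_that("level crossings recover closed-form positions", {
  # triangle: peak 100 at 0, zero at +/-10
  x <- seq(-10, 10, by = 0.5)
  tri <- beam_profile(x, 100 * pmax(0, 1 - abs(x) / 10))
  expect_equal(unname(level_crossings(tri, 50)), c(-5, 5))

  # logistic edges at +/-5, width 0.25: 80% of plateau at 5 - 0.25*ln(4)
  p <- flat_top(e = 5, w = 0.25, step = 0.01)
  cr <- level_crossings(p, 80)
  expect_equal(unname(cr), c(-(5 - 0.25 * log(4)), 5 - 0.25 * log(4)),
               tolerance = 1e-3)
  # fine-grid brute force within half a coarse grid step
  coarse <- flat_top(e = 5, w = 0.25, step = 0.08)
  xf <- seq(0, 9, by = 1e-3)
  df <- 100 / ((1 + exp((xf - 5) / 0.25)) * (1 + exp(-(xf + 5) / 0.25)))
  brute <- xf[which.min(abs(df - 80))]
  expect_lt(abs(level_crossings(coarse, 80)[["x_right"]] - brute), 0.04)

  expect_error(level_crossings(p, 200), "not crossed")
})

test_that("classify_regions delineates field, penumbra and primary region", {
  p <- make_profile(beam_spec("unflattened", field_size = 10), grid_step = 0.1)
  r <- classify_regions(p, mode = "unflattened")
  expect_equal(r$field_size, 10, tolerance = 0.1 / 10)
  expect_equal(r$field_size, r$edge_right - r$edge_left)
  expect_equal(unname(diff(r$primary_interval)), 0.8 * r$field_size)
  expect_equal(r$in_field_boundary, 0.6 * r$field_size)
  expect_gt(r$penumbra_left, 0)

  # logistic edge width w: 80-20 penumbra = 2*ln(4)*w
  ft <- flat_top(e = 5, w = 0.25, step = 0.02)
  rf <- classify_regions(ft, mode = "unflattened")
  expect_equal(rf$penumbra_right, 2 * log(4) * 0.25, tolerance = 0.01)

  # flat-top: unflattened and flattened modes agree within one grid step
  rw <- classify_regions(ft, mode = "flattened")
  expect_lt(abs(rf$field_size - rw$field_size), 0.02)
  expect_lt(abs(rf$penumbra_left - rw$penumbra_left), 0.02)
})

test_that("per-side reference mode uses each side's own inflection dose", {
  # asymmetric flat-top: higher plateau on the left
  x <- seq(-9, 9, by = 0.05)
  d <- 100 / ((1 + exp((x - 5) / 0.25)) * (1 + exp(-(x + 5) / 0.25))) *
    (1 - 0.02 * x)
  p <- beam_profile(x, pmax(d, 0))
  r <- classify_regions(p, mode = "unflattened", combine = "per_side")
  expect_length(r$reference_dose, 2)
  expect_gt(r$reference_dose[["left"]], r$reference_dose[["right"]])
  expect_equal(r$field_size, 10, tolerance = 0.05)
})

test_that("out-of-field dose is the mean tail dose in percent of reference", {
  # constant tail at 4 with plateau 100 -> ~4% of reference
  p <- flat_top(e = 5, w = 0.2, step = 0.05, span = 12, top = 100, tail = 4)
  r <- classify_regions(p, mode = "unflattened")
  oof <- out_of_field_dose(p, r)
  expect_equal(oof, 4, tolerance = 0.1)

  # zero tail -> ~0%
  p0 <- flat_top(e = 5, w = 0.2, step = 0.05, span = 12, tail = 0)
  expect_lt(out_of_field_dose(p0, classify_regions(p0, mode = "unflattened")), 0.1)

  # halving the tail halves the out-of-field dose (narrow edge, small tails,
  # so the reference dose and the edge leakage are unperturbed)
  pa <- flat_top(e = 5, w = 0.1, step = 0.02, span = 12, tail = 0.4)
  pb <- flat_top(e = 5, w = 0.1, step = 0.02, span = 12, tail = 0.2)
  oa <- out_of_field_dose(pa, classify_regions(pa, mode = "unflattened"))
  ob <- out_of_field_dose(pb, classify_regions(pb, mode = "unflattened"))
  expect_equal(ob / oa, 0.5, tolerance = 0.01)

  # profile not extending beyond the boundary errors
  narrow <- flat_top(e = 5, w = 0.2, span = 5.5)
  rn <- classify_regions(narrow, mode = "unflattened")
  expect_error(out_of_field_dose(narrow, rn), "does not extend")
})

test_that("region delineation is dose-scale invariant and translation equivariant", {
  p <- make_profile(beam_spec("unflattened", field_size = 10), grid_step = 0.1)
  r1 <- classify_regions(p, mode = "unflattened")

  p2 <- beam_profile(p$positions, p$doses * 3.7, depth = p$depth)
  r2 <- classify_regions(p2, mode = "unflattened")
  expect_equal(r2$edge_left, r1$edge_left)
  expect_equal(r2$edge_right, r1$edge_right)
  expect_equal(r2$penumbra_left, r1$penumbra_left)
  expect_equal(r2$reference_dose, 3.7 * r1$reference_dose)

  delta <- 1.234
  p3 <- beam_profile(p$positions + delta, p$doses, depth = p$depth)
  r3 <- classify_regions(p3, mode = "unflattened")
  expect_equal(r3$edge_left, r1$edge_left + delta, tolerance = 1e-9)
  expect_equal(r3$edge_right, r1$edge_right + delta, tolerance = 1e-9)
  expect_equal(r3$penumbra_right, r1$penumbra_right, tolerance = 1e-9)
})
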