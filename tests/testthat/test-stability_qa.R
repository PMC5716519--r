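make_test_series <- function(n_frames = 12, ramp_frames = 0, noise = 0,
                             gate = NULL, seed = 5, tilt = 5) {
  make_frames(beam_spec("unflattened", field_size = 25, noise_sd = noise,
                        seed = seed),
              n_frames = n_frames, gate_window = gate,
              ramp_frames = ramp_frames, ramp_tilt = tilt)
}

test_that("percent difference is zero for identical frames and for uniform output scaling", {
  fr <- make_test_series(n_frames = 6)
  pd <- frame_percent_diff(fr)
  expect_equal(max(abs(pd)), 0)

  # a frame scaled uniformly by 1.02 has identical shape: zero difference
  # after per-frame central-axis normalization
  fr2 <- fr
  fr2$frames[3, ] <- fr$frames[3, ] * 1.02
  pd2 <- frame_percent_diff(frame_series(fr2$frames, fr2$positions))
  expect_equal(max(abs(pd2)), 0, tolerance = 1e-10)
})

test_that("a constructed linear tilt shows up as the constructed signed difference", {
  fr <- make_test_series(n_frames = 10, ramp_frames = 1, tilt = 5)
  pd <- frame_percent_diff(fr, reference = fr$frames[5, ])
  x <- fr$positions
  expected <- 100 * (5 / 100 * x / 12.5) / 1  # tilt relative to CAX-normalized ref
  ok <- !attr(pd, "unreliable")
  expect_equal(pd[1, ok], expected[ok], tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(max(abs(pd[2, ok])), 0, tolerance = 1e-10)
})

test_that("ramp-up length finds the unstable prefix exactly and is monotone in tol", {
  stable <- make_test_series(n_frames = 8, ramp_frames = 0, noise = 0.001)
  r0 <- ramp_up_length(stable, tol = 2)
  expect_equal(as.integer(r0), 0L)
  expect_true(attr(r0, "stable"))

  one <- make_test_series(n_frames = 10, ramp_frames = 1, noise = 0.001)
  expect_equal(as.integer(ramp_up_length(one, tol = 2)), 1L)

  # brute-force scan over all suffixes agrees
  pd <- frame_percent_diff(one)
  excl_free <- abs(pd) <= 2
  brute <- 0L
  for (k in seq_len(nrow(pd))) {
    if (all(excl_free[k:nrow(pd), !attr(pd, "unreliable")])) { brute <- k - 1L; break }
  }
  expect_equal(as.integer(ramp_up_length(one, tol = 2)), brute)

  # loosening the tolerance cannot lengthen the unstable prefix
  tols <- c(1, 2, 4, 6, 10)
  lens <- vapply(tols, function(t) as.integer(ramp_up_length(one, tol = t)),
                 integer(1))
  expect_true(all(diff(lens) <= 0))

  # a series that never settles is flagged: every second frame tilted, so
  # all frames deviate from the mean profile
  always <- make_test_series(n_frames = 6, ramp_frames = 1, gate = 2 * 0.072)
  ra <- ramp_up_length(always, tol = 2)
  expect_false(attr(ra, "stable"))
  expect_equal(as.integer(ra), 6L)
})

test_that("gating-cycle period equals the construction period and the gate arithmetic", {
  # 0.5 s window at 0.072 s frames: 7 recorded frames per beam-on cycle
  fr <- make_test_series(n_frames = 70, ramp_frames = 1, noise = 0.002,
                         gate = 0.5, seed = 3)
  res <- gating_cycle_period(fr, tol = 2)
  expect_equal(res$period_frames, 7)
  expect_equal(res$expected_frames, 0.5 / 0.072)

  # noiseless constructed period-5 series is recovered exactly
  fr5 <- make_test_series(n_frames = 40, ramp_frames = 1,
                          gate = 5 * 0.072, seed = 2)
  expect_equal(gating_cycle_period(fr5, tol = 2)$period_frames, 5)

  # autocorrelation oracle: the first strong autocorrelation peak of the
  # per-frame max-deviation trace sits at the detected period
  pd <- frame_percent_diff(fr)
  trace <- apply(abs(pd[, !attr(pd, "unreliable"), drop = FALSE]), 1, max)
  ac <- stats::acf(trace, lag.max = 10, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 7)

  expect_error(gating_cycle_period(make_test_series(n_frames = 10)), "onsets")
})

test_that("qa_trend summarizes offsets, strict exceedances and histograms", {
  zero <- qa_series(seq(as.Date("2020-01-01"), by = "day", length.out = 4),
                    rep(0, 4))
  tr0 <- qa_trend(zero)
  expect_equal(tr0$output_offset$n_exceed, 0)
  expect_equal(tr0$output_offset$mean, 0)
  expect_equal(tr0$output_offset$sd, 0)

  # readings exactly at tolerance pass; beyond it fail
  s <- qa_series(seq(as.Date("2020-01-01"), by = "day", length.out = 5),
                 c(3.1, -3.1, 3.0, 0, 0), tolerance = 3)
  tr <- qa_trend(s)
  expect_equal(tr$output_offset$n_exceed, 2)
  expect_equal(tr$output_offset$exceed_dates, s$dates[1:2])
  expect_equal(sum(tr$output_offset$histogram$count), 5)

  # symmetry columns get their own summaries; histogram counts sum to n
  qa <- make_qa_series(0.6, 0.99, 400, seed = 9)
  qa2 <- qa_series(qa$dates, qa$output_offset,
                   sym_cp = qa$output_offset * 1.5,
                   sym_ip = qa$output_offset - 0.2)
  tr2 <- qa_trend(qa2)
  expect_equal(sum(tr2$sym_cp$histogram$count), 400)
  expect_equal(sum(tr2$sym_ip$histogram$count), 400)
  expect_equal(tr2$output_offset$sd, stats::sd(qa$output_offset))
})

test_that("variability comparison is a two-sided F test validated by permutation", {
  a <- make_qa_series(0.6, 1.0, 80, seed = 21)
  b <- make_qa_series(0.6, 1.25, 80, seed = 22)
  res <- compare_variability(a, b)
  expect_true(res$p_value > 0 && res$p_value < 1)

  # permutation oracle on the same data: shuffle centred residuals, compare
  # |log variance ratio|
  av <- a$output_offset - mean(a$output_offset)
  bv <- b$output_offset - mean(b$output_offset)
  pool <- c(av, bv)
  obs <- abs(log(var(av) / var(bv)))
  set.seed(99)
  perm <- replicate(1e4, {
    idx <- sample(length(pool), length(av))
    abs(log(var(pool[idx]) / var(pool[-idx])))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(res$p_value - p_perm), 0.02)

  # identical series: F statistic 1, p = 1
  same <- compare_variability(a, a)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)

  const <- qa_series(a$dates, rep(1, 80))
  expect_error(compare_variability(a, const), "zero variance")
})
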