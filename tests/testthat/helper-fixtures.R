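# analytic fixtures shared across test files

# flat-top profile with logistic edges at +/- e (plateau `top`, tail `tail`)
flat_top <- function(e = 5, w = 0.25, step = 0.05, span = e + 4, top = 100,
                     tail = 0, depth = 10, ssd = 100) {
  x <- seq(-span, span, by = step)
  d <- top / ((1 + exp((x - e) / w)) * (1 + exp(-(x + e) / w))) + tail
  beam_profile(x, d, depth = depth, ssd = ssd)
}

# cone-shaped FFF-like profile without the generator's edge compensation
cone_profile <- function(fs = 10, w = 0.3, slope = 0.04, step = 0.1,
                         span = 0.6 * fs + 5, depth = 10) {
  x <- seq(-span, span, by = step)
  d <- 100 * pmax(0, 1 - slope * abs(x)) /
    ((1 + exp((x - fs / 2) / w)) * (1 + exp(-(x + fs / 2) / w)))
  beam_profile(x, d, depth = depth)
}
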