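no_adapt <- list(amplitude = c(0, -0.05, 1), width = c(0, -0.05, 1))

test_that("a unit sitting on an electrode renders its full amplitude there", {
  lay <- make_layout(1, 2, 17.8)
  u <- make_unit(1, "somatic_type1", c(lay$x[1], lay$y[1]),
                 amplitude_uV = 150, adaptation = no_adapt)
  rec <- render_recording(lay, list(u), list(0.05), noise_sd = 0,
                          duration = 0.1)
  expect_equal(min(rec$traces[, 1]), -150, tolerance = 1e-9)
})

test_that("amplitude decays exponentially with distance from the origin", {
  lay <- make_layout(1, 2, 25)   # second electrode at d = 25 um
  u <- make_unit(1, "somatic_type1", c(lay$x[1], lay$y[1]),
                 amplitude_uV = 150, decay_um = 25, adaptation = no_adapt)
  rec <- render_recording(lay, list(u), list(0.05), noise_sd = 0,
                          duration = 0.1)
  expect_equal(min(rec$traces[, 2]), -150 * exp(-1), tolerance = 1e-9)
})

test_that("peak amplitude is monotonically nonincreasing in distance", {
  lay <- make_layout(1, 8, 20)
  u <- make_unit(1, "somatic_type1", c(lay$x[1], lay$y[1]),
                 adaptation = no_adapt)
  rec <- render_recording(lay, list(u), list(0.05), noise_sd = 0,
                          duration = 0.1)
  peaks <- apply(rec$traces, 2, function(x) abs(min(x)))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("rendering is bit-identical for the same seed", {
  blk1 <- single_unit_block(duration = 2, seed = 9)
  blk2 <- single_unit_block(duration = 2, seed = 9)
  expect_identical(blk1$recording$traces, blk2$recording$traces)
})

test_that("adaptation modulates per-spike amplitude as g(cFR)/g(0)", {
  lay <- make_layout(1, 1, 17.8)
  p_amp <- c(0.30, -0.05, 0.70)
  u <- make_unit(1, "somatic_type1", c(lay$x[1], lay$y[1]),
                 amplitude_uV = 100,
                 adaptation = list(amplitude = p_amp, width = c(0, -0.05, 1)))
  st <- seq(0.05, by = 0.01, length.out = 20)   # steady 100 Hz burst
  rec <- render_recording(lay, list(u), list(st), noise_sd = 0,
                          duration = 0.5)
  cfr <- continuous_firing_rate(st, 0.1)$cfr_hz
  g <- function(x) p_amp[1] * exp(p_amp[2] * x) + p_amp[3]
  fs <- rec$sampling_rate
  for (j in c(1, 5, 20)) {
    p <- round(st[j] * fs) + 1L
    seg <- rec$traces[(p - 5):(p + 5), 1]
    expect_equal(min(seg), -100 * g(cfr[j]) / g(0), tolerance = 1e-6)
  }
})

test_that("invalid unit/train combinations are rejected", {
  lay <- make_layout(1, 2)
  u <- make_unit(1, "somatic_type1", c(0, 0))
  expect_error(render_recording(lay, list(u), list(), noise_sd = 0),
               "one spike train per unit")
  expect_error(render_recording(lay, list(u), list(5), noise_sd = 0,
                                duration = 1), "inside the recording")
  expect_error(render_recording(lay, list(u), list(0.1), noise_sd = 5,
                                duration = 1), "seed")
})

test_that("unit construction enforces the soma-distance geometry", {
  expect_error(make_unit(1, "somatic_type1", c(0, 0),
                         soma_position = c(100, 0)), "within 50 um")
  expect_error(make_unit(1, "neuritic_type4", c(0, 0),
                         soma_position = c(30, 0)), "more than 50 um")
  u <- make_unit(1, "neuritic_type4", c(0, 0))
  expect_null(u$soma_position)   # isolated neurite
})
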