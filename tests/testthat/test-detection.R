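test_that("band-pass removes DC, preserves the passband, attenuates the stopband", {
  fs <- 20000
  t <- (0:(fs - 1)) / fs
  expect_lt(max(abs(bandpass(rep(5, fs), fs))), 1e-9)
  mid <- 2000:18000   # avoid edges
  y1500 <- bandpass(sin(2 * pi * 1500 * t), fs)
  expect_gt(max(abs(y1500[mid])), 0.95)
  y50 <- bandpass(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y50[mid])), 10^(-20 / 20))   # >= 20 dB down
  expect_error(bandpass(rnorm(100), fs, low = 3000, high = 500), "invalid band")
})

test_that("noise sd estimate is accurate and robust to spike contamination", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(1e5, sd = 10)
    expect_lt(abs(estimate_noise_sd(x) - 10), 0.3)
    spikes <- sample(1e5, 1e3)          # 1% large deflections
    xs <- x; xs[spikes] <- xs[spikes] - 200
    expect_lt(abs(estimate_noise_sd(xs) - 10) / 10, 0.05)
  }
  expect_equal(estimate_noise_sd(numeric(2000)), 0)
  expect_error(estimate_noise_sd(rnorm(100)), "too short")
})

test_that("a single suprathreshold spike is detected at its trough sample", {
  fs <- 20000
  w <- two_lobe(420, 1e6 / fs)          # biphasic, unit depth
  trough <- which.min(w)
  trace <- numeric(fs)
  trace <- insert_spikes(trace, 80 * w, 5000, trough)
  ev <- detect_events(trace, fs, noise_sd = 10)    # 8 sigma at 5 sigma threshold
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_sample, 5000)
})

test_that("spikes closer than the 0.8 ms blanking window merge to one event", {
  fs <- 20000
  w <- two_lobe(420, 1e6 / fs)
  trough <- which.min(w)
  trace <- numeric(fs)
  trace <- insert_spikes(trace, 80 * w, c(5000, 5010), trough)  # 0.5 ms apart
  ev <- detect_events(trace, fs, noise_sd = 10)
  expect_equal(nrow(ev), 1)
})

test_that("false-positive rate on pure noise stays below 0.5 Hz", {
  fs <- 20000
  set.seed(7)
  trace <- bandpass(rnorm(20 * fs, sd = 10), fs)
  ev <- detect_events(trace, fs)
  expect_lt(nrow(ev) / 20, 0.5)
})

test_that("event count is monotonically nonincreasing in the threshold multiple", {
  fs <- 20000
  set.seed(8)
  trace <- bandpass(rnorm(10 * fs, sd = 10), fs)
  counts <- vapply(c(2, 3, 4, 5, 6),
                   function(k) nrow(detect_events(trace, fs, k_threshold = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("8-sigma spikes are found with >= 99% sensitivity and <= 0.15 ms timing error", {
  fs <- 20000
  set.seed(9)
  noise_sd <- 10
  n <- 30 * fs
  w <- make_template_waveform("neuritic_type4", fs)
  trough <- attr(w, "trough_index")
  true_pos <- seq(2000, n - 2000, by = 3000)     # 150 ms spacing, 199 spikes
  trace <- insert_spikes(rnorm(n, sd = noise_sd),
                         8 * noise_sd * w / abs(min(w)), true_pos, trough)
  filt <- bandpass(trace, fs)
  ev <- detect_events(filt, fs)
  tol <- round(0.15e-3 * fs)
  hits <- vapply(true_pos, function(p) any(abs(ev$peak_sample - p) <= tol),
                 logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("activity flag is strict at the 0.2 Hz boundary", {
  am <- activity_map(c(a = 12L, b = 13L, c = 0L), duration = 60)
  expect_equal(am$firing_rate_hz, c(0.2, 13 / 60, 0))
  expect_identical(am$active, c(FALSE, TRUE, FALSE))
  expect_error(activity_map(c(1L), duration = 0), "positive")
})

test_that("with zero noise, detection recovers all true spikes of a rendered unit", {
  blk <- single_unit_block(duration = 10, noise_sd = 0, seed = 21)
  rec <- blk$recording
  center_col <- which.min(layout_distances(blk$layout, blk$origin[1],
                                           blk$origin[2]))
  filt <- bandpass(rec$traces[, center_col], rec$sampling_rate)
  ev <- detect_events(filt, rec$sampling_rate, noise_sd = 1)  # 5 uV threshold
  tol <- round(0.15e-3 * rec$sampling_rate)
  true_samples <- round(blk$spike_times * rec$sampling_rate) + 1L
  hits <- vapply(true_samples, function(p)
    any(abs(ev$peak_sample - p) <= tol), logical(1))
  expect_equal(mean(hits), 1)
})
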