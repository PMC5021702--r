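test_that("cFR recursion matches hand evaluation and its analytic fixed point", {
  # two-spike case: cFR = (1 - e^-1) / 0.1
  cf <- continuous_firing_rate(c(0, 0.1), tau = 0.1)
  expect_equal(cf$cfr_hz[1], 0)
  expect_equal(cf$cfr_hz[2], (1 - exp(-1)) * 10, tolerance = 1e-12)
  # constant ISI converges to exactly 1/dt
  for (dt in c(0.005, 0.02, 0.1)) {
    st <- seq(0, by = dt, length.out = 2000)
    cf <- continuous_firing_rate(st, tau = 0.1)
    expect_equal(tail(cf$cfr_hz, 1), 1 / dt, tolerance = 1e-12)
  }
  # huge interval: d -> 0, cFR -> 1/dt ~ 0
  cf <- continuous_firing_rate(c(0, 10), tau = 0.1)
  expect_equal(cf$cfr_hz[2], 1 / 10, tolerance = 1e-9)
  expect_error(continuous_firing_rate(c(0, 0.1, 0.1)), "strictly increasing")
})

test_that("cFR is invariant to a global time shift of the train", {
  st <- make_spike_train(20, 1, 100, 5, seed = 4)
  a <- continuous_firing_rate(st)$cfr_hz
  b <- continuous_firing_rate(st + 123.456)$cfr_hz
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("AR follows its defining formula in closed-form cases", {
  st <- make_spike_train(120, 1, 100, 5, seed = 6)
  cfr <- continuous_firing_rate(st)$cfr_hz
  # shrinking amplitude: y_inf 50, y_c 50 -> AR -50%
  y <- 50 * exp(-0.05 * cfr) + 50
  expect_equal(fit_adaptation(y, cfr)$ar_percent, -50, tolerance = 1e-3)
  # widening: y_inf 300, y_c -60 -> AR +25%
  y <- -60 * exp(-0.05 * cfr) + 300
  expect_equal(fit_adaptation(y, cfr)$ar_percent, 25, tolerance = 1e-3)
  # rate-independent feature -> AR exactly 0
  expect_equal(fit_adaptation(rep(80, length(cfr)), cfr)$ar_percent, 0)
})

test_that("AR is recovered within 5 points from noisy per-spike data", {
  errs <- vapply(1:5, function(s) {
    st <- make_spike_train(120, 1, 100, 5, seed = s)
    cfr <- continuous_firing_rate(st)$cfr_hz
    set.seed(s + 500)
    y <- (50 * exp(-0.05 * cfr) + 50) * (1 + rnorm(length(cfr), 0, 0.02))
    abs(fit_adaptation(y, cfr)$ar_percent - (-50))
  }, numeric(1))
  expect_lt(max(errs), 5)
})

test_that("the adaptation fit exposes standard model methods", {
  st <- make_spike_train(60, 1, 100, 5, seed = 8)
  cfr <- continuous_firing_rate(st)$cfr_hz
  set.seed(9)
  y <- (30 * exp(-0.05 * cfr) + 70) * (1 + rnorm(length(cfr), 0, 0.01))
  fit <- fit_adaptation(y, cfr, feature_name = "amplitude")
  expect_s3_class(fit, "adaptation_fit")
  expect_named(coef(fit), c("y_c", "b", "y_inf"))
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(predict(fit, 0), sum(coef(fit)[c("y_c", "y_inf")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_output(print(fit), "adaptation rate")
})

test_that("group comparison reproduces exact Mann-Whitney results", {
  # disjoint small samples: U = 0, exact two-tailed p = 2/choose(6,3)
  res <- compare_groups(c(1, 2, 3, 10, 11, 12),
                        rep(c("a", "b"), each = 3))
  expect_equal(res$tests$U, 0)
  expect_equal(res$tests$p_two_tailed, 0.1, tolerance = 1e-12)
  # identical groups: p near 1
  res2 <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(res2$tests$p_two_tailed, 0.99)
})

test_that("group comparison has power against separated AR distributions", {
  set.seed(10)
  ar <- c(rnorm(50, -30, 5), rnorm(50, 0, 5))
  res <- compare_groups(ar, rep(c("somatic", "neuritic"), each = 50))
  expect_lt(res$tests$p_two_tailed, 0.001)
  expect_equal(nrow(res$summaries), 2)
})

test_that("undersized groups are skipped with a warning", {
  expect_warning(
    res <- compare_groups(c(1, 2, 3, 4, 5, 6, 9),
                          c("a", "a", "a", "b", "b", "b", "c")),
    "undersized")
  expect_equal(nrow(res$tests), 1)   # only a-vs-b compared
  expect_error(suppressWarnings(
    compare_groups(c(1, 2, 9), c("a", "a", "b"))), "at least 2 groups")
})
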