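# build stacked-snippet matrices directly: two waveform clusters in
# snippet space with centroid separation `sep` times the per-dimension sd
make_two_cluster_stack <- function(n_per = 200, dim = 150, sep = 10,
                                   noise_sd = 1, seed = 1) {
  set.seed(seed)
  dir <- rnorm(dim); dir <- dir / sqrt(sum(dir^2))
  X <- rbind(
    t(replicate(n_per, rnorm(dim, sd = noise_sd))),
    t(replicate(n_per, sep * noise_sd * dir + rnorm(dim, sd = noise_sd))))
  # interleave the two units in time: rows 1, n+1, 2, n+2, ...
  map <- as.vector(rbind(seq_len(n_per), n_per + seq_len(n_per)))
  X <- X[map, , drop = FALSE]
  attr(X, "times_s") <- seq_len(2 * n_per) * 0.01
  attr(X, "truth") <- rep(1:2, n_per)
  X
}

test_that("align_and_stack merges coincident events and keeps disjoint ones", {
  fs <- 20000
  n <- fs
  w <- two_lobe(420, 1e6 / fs)
  trough <- which.min(w)
  tr <- matrix(0, n, 3)
  # one spike visible on all three electrodes (strongest on ch 2)
  for (ch in 1:3) tr[, ch] <- insert_spikes(tr[, ch], c(60, 100, 40)[ch] * w,
                                            5000, trough)
  # a second, disjoint spike only on channel 1
  tr[, 1] <- insert_spikes(tr[, 1], 80 * w, 9000, trough)
  evs <- lapply(1:3, function(ch) detect_events(tr[, ch], fs, noise_sd = 5))
  stacked <- align_and_stack(evs, tr, fs)
  n_win <- round(2.5e-3 * fs)
  expect_equal(ncol(stacked), 3 * n_win)
  expect_equal(nrow(stacked), 2)        # merged triple + singleton
  # zero events give a valid empty matrix
  empty <- align_and_stack(lapply(1:3, function(i)
    detect_events(numeric(n) , fs, noise_sd = 5)), tr, fs)
  expect_equal(nrow(empty), 0)
})

test_that("well-separated clusters are recovered with zero misassignments", {
  X <- make_two_cluster_stack(seed = 11)
  set.seed(12)
  units <- cluster_events(X)
  expect_equal(length(units), 2)
  truth <- attr(X, "truth")
  # oracle: brute-force nearest-centroid labelling
  c1 <- colMeans(X[truth == 1, ]); c2 <- colMeans(X[truth == 2, ])
  oracle <- apply(X, 1, function(r)
    which.min(c(sum((r - c1)^2), sum((r - c2)^2))))
  got <- integer(nrow(X))
  for (u in units) got[u$member_event_ids] <- u$unit_id
  err <- min(mean(got != oracle), mean(got != 3 - oracle))
  expect_equal(err, 0)
})

test_that("an overclustered homogeneous cloud merges back to one unit", {
  set.seed(13)
  Y <- t(replicate(300, rnorm(150)))
  attr(Y, "times_s") <- seq_len(300) * 0.01
  units <- cluster_events(Y, kmeans_k = 8)
  expect_equal(length(units), 1)
})

test_that("indistinguishable units collapse and RPV reflects the merged train", {
  set.seed(14)
  n <- 200
  Y <- matrix(rnorm(n * 150, sd = 0.01), n, 150) # near-identical waveforms
  # two interleaved trains 0.4 ms apart -> merged ISIs below 1.5 ms
  t1 <- seq_len(n / 2) * 0.05
  times <- sort(c(t1, t1 + 0.4e-3))
  attr(Y, "times_s") <- times
  units <- cluster_events(Y, kmeans_k = 4)
  expect_equal(length(units), 1)
  expect_gt(units[[1]]$rpv_fraction, 0.4)
})

test_that("sorting is invariant to uniform amplitude scaling of all snippets", {
  X <- make_two_cluster_stack(n_per = 100, seed = 15)
  set.seed(16); u1 <- cluster_events(X)
  Xs <- X * 7.3
  attr(Xs, "times_s") <- attr(X, "times_s")
  set.seed(16); u2 <- cluster_events(Xs)
  expect_equal(length(u1), length(u2))
  expect_identical(lapply(u1, `[[`, "member_event_ids"),
                   lapply(u2, `[[`, "member_event_ids"))
})

test_that("two-unit recovery succeeds in at least 95% of seeded runs", {
  ok <- vapply(1:50, function(s) {
    X <- make_two_cluster_stack(n_per = 60, dim = 60, seed = 100 + s)
    set.seed(200 + s)
    length(cluster_events(X)) == 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("fewer events than miniclusters reduces k with a warning", {
  set.seed(17)
  Z <- matrix(rnorm(5 * 30), 5, 30)
  attr(Z, "times_s") <- 1:5 * 0.01
  expect_warning(units <- cluster_events(Z, kmeans_k = 8), "reducing")
  expect_gte(length(units), 1)
})

test_that("oversampling is exact on the original grid and accurate off it", {
  fs <- 20000
  n <- 2000                                    # integer cycle count
  x <- sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  y <- oversample(x, fs, 320000)
  expect_equal(length(y), 16 * n)
  expect_lt(max(abs(y[seq(1, length(y), 16)] - x)), 1e-9)
  analytic <- sin(2 * pi * 1000 * (0:(16 * n - 1)) / 320000)
  expect_lt(max(abs(y - analytic)), 0.01)      # within 1% of peak
  expect_equal(oversample(rep(3, 50), fs, 320000), rep(3, 800))
  expect_error(oversample(x, 20000, 30000), "integer multiple")
})

test_that("noise-free footprints equal the rendered waveform with the nearest representative electrode", {
  blk <- single_unit_block(kind = "neuritic_type4", duration = 10,
                           noise_sd = 0, seed = 31)
  rec <- blk$recording
  fp <- footprint(blk$spike_times, rec$traces, rec$sampling_rate,
                  electrode_ids = blk$layout$electrode_id)
  nearest <- blk$layout$electrode_id[
    which.min(layout_distances(blk$layout, blk$origin[1], blk$origin[2]))]
  expect_equal(fp$representative_electrode, nearest)
  # type 4 has no adaptation, so at the acquisition grid the STA equals
  # the rendered waveform exactly (averaging identical snippets)
  on_grid <- fp$sta[seq(1, nrow(fp$sta), by = 16), fp$representative_column]
  expect_equal(min(on_grid), -blk$unit$amplitude_uV, tolerance = 1e-6)
  # and the interpolated STA stays within band-limited ringing of it
  expect_equal(min(fp$sta[, fp$representative_column]),
               -blk$unit$amplitude_uV, tolerance = 2e-3)
})

test_that("STA noise shrinks as one over the square root of the spike count", {
  fs <- 20000
  n_win <- 50
  sd_of_sta <- function(n_spikes, seed) {
    set.seed(seed)
    # pure-noise snippets: STA residual sd estimates noise/sqrt(n)
    sta <- colMeans(matrix(rnorm(n_spikes * n_win, sd = 10), n_spikes))
    sd(sta)
  }
  ratios <- vapply(1:20, function(s) sd_of_sta(25, s) / sd_of_sta(400, s + 999),
                   numeric(1))
  expect_lt(abs(mean(ratios) - 4) / 4, 0.2)
})

test_that("unit acceptance keeps only low-RPV, high-count clusters", {
  units <- list(
    list(unit_id = 1, n_spikes = 300, rpv_fraction = 0.001),
    list(unit_id = 2, n_spikes = 300, rpv_fraction = 0.02),
    list(unit_id = 3, n_spikes = 50, rpv_fraction = 0))
  expect_equal(vapply(accept_units(units), `[[`, 0, "unit_id"), 1)
})
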