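#' Merge and align events from a three-electrode sorting group
#'
#' Spike sorting is performed on three neighbouring electrodes. Threshold
#' crossings occurring within `merge_window` of each other across the
#' three electrodes are treated as one multi-channel event; each event is
#' aligned on the negative peak of its largest-amplitude channel, and the
#' three snippets are concatenated into one row.
#'
#' @param events_list List of 3 event tables from [detect_events()] (one
#'   per electrode, in the same order as `traces`).
#' @param traces Numeric matrix, samples x 3 electrodes (filtered).
#' @param sampling_rate Hz.
#' @param window Snippet length in seconds (default 2.5 ms).
#' @param merge_window Cross-electrode duplicate window in seconds
#'   (default 0.5 ms).
#' @return Matrix with one row per multi-channel event (3 x window
#'   samples, channels concatenated), with attributes `times_s`,
#'   `align_sample` and `sampling_rate`. Zero events give a 0-row matrix.
#' @export
align_and_stack <- function(events_list, traces, sampling_rate,
                            window = 2.5e-3, merge_window = 0.5e-3) {
  if (length(events_list) != 3) stop("exactly 3 electrode event streams required")
  traces <- as.matrix(traces)
  if (ncol(traces) != 3) stop("traces must have 3 columns")
  n <- nrow(traces)
  n_win <- round(window * sampling_rate)
  pre <- floor(n_win / 2); post <- n_win - pre - 1L

  ev <- do.call(rbind, lapply(seq_along(events_list), function(ch) {
    e <- events_list[[ch]]
    if (nrow(e) == 0) return(NULL)
    data.frame(channel = ch, peak_sample = e$peak_sample, peak_uV = e$peak_uV)
  }))
  if (is.null(ev) || nrow(ev) == 0) {
    out <- matrix(numeric(0), 0, 3 * n_win)
    attr(out, "times_s") <- numeric(0)
    attr(out, "align_sample") <- integer(0)
    attr(out, "sampling_rate") <- sampling_rate
    return(out)
  }
  ev <- ev[order(ev$peak_sample), , drop = FALSE]
  gap <- round(merge_window * sampling_rate)
  grp <- cumsum(c(1L, as.integer(diff(ev$peak_sample) > gap)))

  rows <- list(); times <- numeric(0); aligns <- integer(0)
  for (g in unique(grp)) {
    sub <- ev[grp == g, , drop = FALSE]
    lead <- sub[which.max(abs(sub$peak_uV)), ]
    p <- lead$peak_sample
    if (p - pre < 1L || p + post > n) next
    rows[[length(rows) + 1L]] <-
      as.numeric(traces[(p - pre):(p + post), ])
    times <- c(times, (p - 1L) / sampling_rate)
    aligns <- c(aligns, p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, 3 * n_win)
  attr(out, "times_s") <- times
  attr(out, "align_sample") <- aligns
  attr(out, "sampling_rate") <- sampling_rate
  out
}

# Interface-energy connection matrix between clusters: pairwise
# Gaussian similarities exp(-d_ij^2 / (2 h^2)) summed between (and
# within) clusters, normalised per pair count, connection strength
# e_kl / sqrt(e_kk * e_ll). The Gaussian kernel decays fast enough that
# well-separated clusters have near-zero connection while touching
# partitions of one cloud stay strongly connected. Singleton clusters
# take within-energy 1 (a point is maximally similar to itself).
interface_energy_matrix <- function(d, labels, h) {
  ids <- sort(unique(labels))
  k <- length(ids)
  sim <- exp(-d^2 / (2 * h^2))
  E <- matrix(0, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k)) {
    ia <- which(labels == ids[a])
    for (b in a:k) {
      ib <- which(labels == ids[b])
      if (a == b) {
        if (length(ia) < 2) { E[a, a] <- 1; next }
        s <- sim[ia, ia, drop = FALSE]
        E[a, a] <- sum(s[upper.tri(s)]) / (length(ia) * (length(ia) - 1) / 2)
      } else {
        E[a, b] <- E[b, a] <-
          sum(sim[ia, ib, drop = FALSE]) / (length(ia) * length(ib))
      }
    }
  }
  C <- E / sqrt(diag(E) %o% diag(E))
  diag(C) <- 0
  C
}

#' Cluster stacked snippets into sorted units
#'
#' PCA projection, K-means overclustering into `kmeans_k` miniclusters,
#' then iterative aggregation of minicluster pairs whose normalized
#' interface energy exceeds `agg_criterion` (energies recomputed after
#' each merge, until no pair exceeds the criterion). Similarity between
#' events is a Gaussian kernel whose length scale is half the median
#' nearest-neighbour distance in PC space. Each
#' resulting unit reports its refractory-period-violation fraction at a
#' 1.5 ms floor.
#'
#' @param stacked Snippet matrix from [align_and_stack()] (rows = events).
#' @param times_s Event times (defaults to the `times_s` attribute).
#' @param n_pc Number of principal components (default 10).
#' @param kmeans_k Miniclusters before aggregation (default 8). Reduced,
#'   with a warning, when there are fewer events than miniclusters.
#' @param agg_criterion Aggregation stop criterion (default 0.001); higher
#'   values allow more aggregation.
#' @param refractory Refractory floor for RPV accounting, seconds
#'   (default 1.5 ms).
#' @return List of units; each has `unit_id`, `spike_times`,
#'   `member_event_ids`, `n_spikes`, `rpv_fraction`.
#' @export
cluster_events <- function(stacked, times_s = attr(stacked, "times_s"),
                           n_pc = 10, kmeans_k = 8, agg_criterion = 0.001,
                           refractory = 1.5e-3) {
  n <- nrow(stacked)
  if (n == 0) return(list())
  if (n < kmeans_k) {
    warning("fewer events (", n, ") than kmeans_k; reducing to ", n)
    kmeans_k <- n
  }
  n_pc <- min(n_pc, ncol(stacked), n)
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]

  labels <- if (kmeans_k == 1 || n == 1) rep(1L, n)
    else if (kmeans_k >= n) seq_len(n)   # every event its own minicluster
    else stats::kmeans(scores, centers = kmeans_k, nstart = 5,
                       iter.max = 100)$cluster

  if (length(unique(labels)) > 1) {
    d <- as.matrix(stats::dist(scores))
    nn <- apply(d + diag(Inf, n), 1, min)
    h <- stats::median(nn) / 2
    if (h <= 0) h <- mean(d[d > 0]) / 2
    if (!is.finite(h) || h <= 0) h <- 1
    repeat {
      C <- interface_energy_matrix(d, labels, h)
      if (max(C) <= agg_criterion) break
      idx <- which(C == max(C), arr.ind = TRUE)[1, ]
      ids <- sort(unique(labels))
      labels[labels == ids[idx[2]]] <- ids[idx[1]]
      if (length(unique(labels)) == 1) break
    }
  }

  ids <- sort(unique(labels))
  lapply(seq_along(ids), function(u) {
    members <- which(labels == ids[u])
    st <- sort(times_s[members])
    rpv <- if (length(st) > 1) mean(diff(st) < refractory) else 0
    list(unit_id = u, spike_times = st, member_event_ids = members,
         n_spikes = length(st), rpv_fraction = rpv)
  })
}

#' Automatic cluster acceptance filter
#'
#' Keeps well-isolated units: refractory-period-violation fraction below
#' `max_rpv` and at least `min_spikes` spikes. This codifies, as a
#' reproducible rule, the manual supervised evaluation step of classic
#' sorting workflows.
#'
#' @param units List of units from [cluster_events()].
#' @param max_rpv Maximum RPV fraction (default 0.01).
#' @param min_spikes Minimum spike count (default 100).
#' @return Filtered unit list.
#' @export
accept_units <- function(units, max_rpv = 0.01, min_spikes = 100) {
  Filter(function(u) u$rpv_fraction < max_rpv && u$n_spikes >= min_spikes,
         units)
}

#' Band-limited (Fourier) oversampling
#'
#' Resamples a series to an integer multiple of its rate by zero-padding
#' the discrete Fourier spectrum (with Nyquist-bin splitting), i.e. exact
#' band-limited sinc interpolation on the periodic extension. Original
#' samples are reproduced exactly at their positions.
#'
#' @param trace Voltage series.
#' @param sampling_rate Hz.
#' @param target_rate Hz; must be an integer multiple of `sampling_rate`.
#' @return Numeric series of length `length(trace) * target_rate /
#'   sampling_rate`.
#' @export
oversample <- function(trace, sampling_rate, target_rate = 320000) {
  r <- target_rate / sampling_rate
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("target_rate must be an integer multiple of sampling_rate")
  r <- as.integer(round(r))
  if (r == 1L) return(as.numeric(trace))
  n <- length(trace)
  m <- n * r
  X <- stats::fft(trace)
  Y <- complex(m)
  if (n %% 2L == 0L) {
    h <- n %/% 2L
    Y[1:h] <- X[1:h]
    Y[h + 1L] <- X[h + 1L] / 2          # split the Nyquist bin
    Y[m - h + 1L] <- X[h + 1L] / 2
    if (h > 1) Y[(m - h + 2L):m] <- X[(h + 2L):n]
  } else {
    h <- (n - 1L) %/% 2L
    Y[1:(h + 1L)] <- X[1:(h + 1L)]
    Y[(m - h + 1L):m] <- X[(h + 2L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Spike-triggered average footprint
#'
#' Averages wideband snippets around a unit's spike times on every
#' electrode of the recording block, yielding the unit's spatial
#' footprint at the oversampled rate. Averaging and band-limited
#' interpolation are both linear and spike times are at acquisition-sample
#' resolution, so the STA is computed at the acquisition rate and
#' oversampled once. The representative electrode is the one whose STA
#' has the largest negative peak.
#'
#' @param spike_times Unit spike times (s), >= 1 spike. Spikes whose
#'   window falls outside the trace are skipped (count reported).
#' @param traces Wideband trace matrix, samples x electrodes.
#' @param sampling_rate Acquisition rate, Hz.
#' @param electrode_ids Electrode ids for the columns (default 0-based).
#' @param window Snippet length, seconds (default 2.5 ms).
#' @param oversample_rate STA output rate, Hz (default 320 kHz).
#' @return `eap_footprint` object: list with `sta` (oversampled samples x
#'   electrodes matrix, uV), `sampling_rate`, `n_spikes`, `n_skipped`,
#'   `electrode_ids`, `representative_electrode` (id) and
#'   `representative_column`.
#' @export
footprint <- function(spike_times, traces, sampling_rate,
                      electrode_ids = NULL, window = 2.5e-3,
                      oversample_rate = 320000) {
  if (length(spike_times) < 1) stop("unit must have at least 1 spike")
  traces <- as.matrix(traces)
  n <- nrow(traces)
  if (is.null(electrode_ids)) electrode_ids <- seq_len(ncol(traces)) - 1L
  n_win <- round(window * sampling_rate)
  pre <- floor(n_win / 2); post <- n_win - pre - 1L
  centers <- round(spike_times * sampling_rate) + 1L
  ok <- centers - pre >= 1L & centers + post <= n
  n_skipped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) == 0) stop("no spike window fits inside the traces")

  sta20 <- matrix(0, n_win, ncol(traces))
  for (p in centers) sta20 <- sta20 + traces[(p - pre):(p + post), , drop = FALSE]
  sta20 <- sta20 / length(centers)

  sta <- apply(sta20, 2, oversample, sampling_rate = sampling_rate,
               target_rate = oversample_rate)
  rep_col <- which.max(abs(apply(sta, 2, min)))
  out <- list(sta = sta, sampling_rate = oversample_rate,
              n_spikes = length(centers), n_skipped = n_skipped,
              electrode_ids = electrode_ids,
              representative_electrode = electrode_ids[rep_col],
              representative_column = rep_col)
  class(out) <- "eap_footprint"
  out
}

#' @export
print.eap_footprint <- function(x, ...) {
  cat(sprintf("EAP footprint: %d electrodes, %d spikes averaged, rep. electrode %d (peak %.1f uV)\n",
              ncol(x$sta), x$n_spikes, x$representative_electrode,
              min(x$sta[, x$representative_column])))
  invisible(x)
}
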