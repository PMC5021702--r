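#' Waveform amplitude
#'
#' Signed amplitude of the main negative peak: `min(sta)`. Valid spikes
#' are negative-going, so the value is negative (in uV for calibrated
#' traces).
#'
#' @param sta Averaged waveform (voltage vector).
#' @return Signed amplitude (negative).
#' @export
sta_amplitude <- function(sta) {
  m <- min(sta)
  if (!is.finite(m) || m >= 0) stop("waveform has no negative peak")
  m
}

#' Waveform half-width
#'
#' Duration of the main negative phase at values below 50% of the
#' negative peak, i.e. the contiguous span around the trough where
#' `sta < 0.5 * min(sta)`. The two 50% crossings are located by linear
#' interpolation between samples for sub-sample precision.
#'
#' @param sta Averaged waveform.
#' @param sample_period_us Sample period in microseconds.
#' @return Half-width in microseconds.
#' @export
sta_half_width <- function(sta, sample_period_us) {
  amp <- sta_amplitude(sta)
  half <- 0.5 * amp                      # negative level
  i0 <- which.min(sta)
  below <- sta < half
  if (!below[i0]) stop("trough does not cross its own half level")
  # walk out from the trough to the last contiguous below-half samples
  l <- i0; while (l > 1L && below[l - 1L]) l <- l - 1L
  r <- i0; while (r < length(sta) && below[r + 1L]) r <- r + 1L
  if (l == 1L || r == length(sta))
    stop("half-level crossing outside the waveform window")
  # linear interpolation at the crossings
  tl <- (l - 1) - (half - sta[l]) / (sta[l - 1L] - sta[l])
  tr <- (r - 1) + (half - sta[r]) / (sta[r + 1L] - sta[r])
  (tr - tl) * sample_period_us
}

#' Trough-peak width
#'
#' Time from the main negative peak to the first positive peak after it:
#' the first strictly positive local maximum following the trough that
#' rises to at least 5% of the trough depth (smaller ripples are treated
#' as noise). Monophasic waveforms have no such peak; `NA` is returned.
#'
#' @param sta Averaged waveform.
#' @param sample_period_us Sample period in microseconds.
#' @param min_prominence Minimum candidate-peak height as a fraction of
#'   |amplitude| (default 0.05).
#' @return Trough-to-peak time in microseconds, or `NA_real_` if no
#'   qualifying positive peak exists.
#' @export
sta_trough_peak_width <- function(sta, sample_period_us,
                                  min_prominence = 0.05) {
  amp <- sta_amplitude(sta)
  i0 <- which.min(sta)
  n <- length(sta)
  if (i0 >= n - 1L) return(NA_real_)
  seg <- sta[(i0 + 1L):n]
  # local maxima strictly inside the segment
  k <- which(diff(sign(diff(seg))) < 0) + 1L
  if (length(k) == 0) return(NA_real_)
  floor_prom <- min_prominence * abs(amp)
  for (j in k) {
    if (seg[j] > 0 && seg[j] >= floor_prom) return(j * sample_period_us)
  }
  NA_real_
}

#' Relative standard deviation (RSTD) of spike waveforms
#'
#' Shape-consistency index: every snippet is normalized by the
#' peak-to-peak amplitude of the mean waveform, the per-sample standard
#' deviation is taken across snippets, and the mean over samples is
#' returned. Identical snippets give 0; heterogeneous (multi-unit) spike
#' collections give large values.
#'
#' @param snippets Matrix, one spike snippet per row (>= 2 rows).
#' @param mean_waveform Average waveform; defaults to the column mean of
#'   `snippets`.
#' @return Dimensionless RSTD (>= 0).
#' @export
sta_rstd <- function(snippets, mean_waveform = colMeans(snippets)) {
  snippets <- as.matrix(snippets)
  if (nrow(snippets) < 2) stop("need at least 2 snippets")
  p2p <- max(mean_waveform) - min(mean_waveform)
  if (p2p <= 0) stop("mean waveform has zero peak-to-peak amplitude")
  norm <- snippets / p2p
  mean(apply(norm, 2, stats::sd))
}

#' All waveform-shape features of an averaged spike
#'
#' @param sta Averaged waveform (uV), e.g. the representative-electrode
#'   STA of a footprint.
#' @param sample_period_us Sample period, microseconds.
#' @param snippets Optional matrix of the contributing spike snippets (for
#'   RSTD; must share the mean waveform's scale, not its sample rate).
#' @param n_spikes Spike count (defaults to `nrow(snippets)`).
#' @return data.frame of class `eap_features`: `amplitude_uV`,
#'   `half_width_us`, `trough_peak_width_us`, `rstd`, `n_spikes`.
#' @export
waveform_features <- function(sta, sample_period_us, snippets = NULL,
                              n_spikes = if (is.null(snippets)) NA_integer_
                                         else nrow(snippets)) {
  out <- data.frame(
    amplitude_uV = sta_amplitude(sta),
    half_width_us = sta_half_width(sta, sample_period_us),
    trough_peak_width_us = sta_trough_peak_width(sta, sample_period_us),
    rstd = if (is.null(snippets)) NA_real_ else sta_rstd(snippets),
    n_spikes = n_spikes)
  class(out) <- c("eap_features", "data.frame")
  out
}
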