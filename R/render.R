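#' Ground-truth synthetic unit
#'
#' Describes one signal source on the array: its canonical waveform kind,
#' the position of its signal origin, the soma position (for somatic
#' kinds the origin itself; for neuritic kinds either absent or more than
#' 50 um away), its peak amplitude at the origin, the exponential spatial
#' decay constant, and the per-feature adaptation parameters used to
#' modulate the spike shape with the continuous firing rate.
#'
#' Default amplitudes place somatic units at 200/180 uV and neuritic
#' units at 120/110 uV at the origin electrode, i.e. somatic sources well
#' above and neuritic sources at the top of the amplitude range typical
#' of axonal signals, so that generated units are detectable and
#' screenable by the analysis chain. Default adaptation (dimensionless
#' multipliers of amplitude/width, as `c(y_c, b, y_inf)` with `g(0) = 1`):
#' somatic amplitude shrinks 30% at high rates and width grows 15%;
#' type 3 shows mild adaptation (-10% amplitude); type 4 none.
#'
#' @param unit_id Integer id.
#' @param kind One of the four template kinds (see
#'   [make_template_waveform()]).
#' @param origin `c(x, y)` position of the signal origin, um.
#' @param soma_position `c(x, y)` um, or `NULL`. Defaults to `origin` for
#'   somatic kinds and `NULL` (isolated neurite) for neuritic kinds.
#' @param amplitude_uV Trough depth at the origin electrode.
#' @param decay_um Exponential spatial decay constant (default 25 um:
#'   signal is near zero beyond ~100 um).
#' @param adaptation List with elements `amplitude` and `width`, each
#'   `c(y_c, b, y_inf)` for the multiplier model `g(x) = y_c e^{b x} +
#'   y_inf`, `g(0) = 1`.
#' @return A `gt_unit` list.
#' @export
make_unit <- function(unit_id, kind, origin, soma_position = NULL,
                      amplitude_uV = NULL, decay_um = 25,
                      adaptation = NULL) {
  kind <- match.arg(kind, template_kinds)
  somatic <- grepl("^somatic", kind)
  if (is.null(amplitude_uV))
    amplitude_uV <- switch(kind, somatic_type1 = 200, somatic_type2 = 180,
                           neuritic_type3 = 120, neuritic_type4 = 110)
  if (is.null(soma_position) && somatic) soma_position <- origin
  if (!is.null(soma_position)) {
    d <- sqrt(sum((soma_position - origin)^2))
    if (somatic && d >= 50)
      stop("somatic units must have their origin within 50 um of the soma")
    if (!somatic && d <= 50)
      stop("neuritic units must be more than 50 um from any soma")
  }
  if (is.null(adaptation))
    adaptation <- switch(kind,
      somatic_type1 = ,
      somatic_type2 = list(amplitude = c(0.30, -0.05, 0.70),
                           width = c(-0.15, -0.05, 1.15)),
      neuritic_type3 = list(amplitude = c(0.10, -0.05, 0.90),
                            width = c(-0.05, -0.05, 1.05)),
      neuritic_type4 = list(amplitude = c(0, -0.05, 1.00),
                            width = c(0, -0.05, 1.00)))
  structure(list(unit_id = unit_id, kind = kind, origin = origin,
                 soma_position = soma_position,
                 amplitude_uV = amplitude_uV, decay_um = decay_um,
                 adaptation = adaptation),
            class = "gt_unit")
}

# evaluate the multiplier model g(x) = y_c e^{bx} + y_inf
adapt_multiplier <- function(p, x) p[1] * exp(p[2] * x) + p[3]

# time-stretch a trough-centred waveform by `s` (s > 1 widens), linear
# interpolation on the original time base
stretch_waveform <- function(w, s, trough_index) {
  n <- length(w)
  t <- (seq_len(n) - trough_index)
  stats::approx(x = t * s, y = w, xout = t, yleft = 0, yright = 0)$y
}

#' Render a synthetic HDMEA recording
#'
#' Adds each unit's spikes to every electrode trace, scaled by
#' `exp(-distance(origin, electrode) / decay_um)`, with the spike's
#' amplitude and width modulated by the unit's adaptation parameters
#' evaluated at the spike's continuous firing rate (so bursts produce
#' shrinking, widening spikes exactly as the adaptation module assumes).
#' Gaussian noise of SD `noise_sd` is then generated independently per
#' sample and band-limited to 25 Hz-3.5 kHz, emulating an on-chip
#' acquisition filter, before being added to the clean spike signal.
#'
#' @param layout An [make_layout()] electrode layout.
#' @param units List of [make_unit()] ground-truth units.
#' @param trains List of spike-time vectors, one per unit.
#' @param noise_sd White-noise SD in uV before band-limiting (>= 0).
#' @param sampling_rate Hz (default 20 kHz).
#' @param duration Seconds; defaults to the last spike time + 50 ms.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param tau cFR decay constant used for the adaptation modulation
#'   (default 0.1 s).
#' @return An `eap_recording` list: `layout`, `sampling_rate`, `traces`
#'   (samples x electrodes, uV), `units`, `spike_times` (per unit),
#'   `soma_table`, `noise_sd`, `duration`.
#' @export
render_recording <- function(layout, units, trains, noise_sd = 10,
                             sampling_rate = 20000, duration = NULL,
                             seed = NULL, tau = 0.1) {
  if (length(units) != length(trains))
    stop("one spike train per unit is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed)) stop("an explicit seed is required")
  if (is.null(duration)) {
    last <- max(c(0, unlist(trains)))
    duration <- last + 0.05
  }
  n <- round(duration * sampling_rate)
  traces <- matrix(0, n, nrow(layout))

  for (k in seq_along(units)) {
    u <- units[[k]]
    st <- trains[[k]]
    if (length(st) == 0) next
    if (any(st < 0 | st >= duration))
      stop("spike times must lie inside the recording interval")
    w0 <- make_template_waveform(u$kind, sampling_rate)
    w0 <- w0 / abs(min(w0))   # amplitude_uV is the rendered trough depth
    i0 <- attr(w0, "trough_index")
    nw <- length(w0)
    cfr <- continuous_firing_rate(st, tau)$cfr_hz
    g_amp0 <- adapt_multiplier(u$adaptation$amplitude, 0)
    g_wid0 <- adapt_multiplier(u$adaptation$width, 0)
    dists <- layout_distances(layout, u$origin[1], u$origin[2])
    gains <- u$amplitude_uV * exp(-dists / u$decay_um)
    el <- which(gains > 1e-6 * u$amplitude_uV)
    if (length(el) == 0) next
    for (j in seq_along(st)) {
      s_amp <- adapt_multiplier(u$adaptation$amplitude, cfr[j]) / g_amp0
      s_wid <- adapt_multiplier(u$adaptation$width, cfr[j]) / g_wid0
      w <- if (abs(s_wid - 1) < 1e-12) w0 else
        stretch_waveform(w0, s_wid, i0)
      w <- w * s_amp
      p <- round(st[j] * sampling_rate) + 1L
      a <- p - i0 + 1L; b <- a + nw - 1L
      wa <- 1L; wb <- nw
      if (a < 1L) { wa <- wa + (1L - a); a <- 1L }
      if (b > n) { wb <- wb - (b - n); b <- n }
      if (a > b) next
      for (e in el)
        traces[a:b, e] <- traces[a:b, e] + gains[e] * w[wa:wb]
    }
  }

  if (noise_sd > 0) {
    noise <- local_seed(seed, matrix(stats::rnorm(n * ncol(traces),
                                                  sd = noise_sd),
                                     n, ncol(traces)))
    bf <- signal::butter(2, c(25, 3500) / (sampling_rate / 2), type = "pass")
    for (e in seq_len(ncol(traces)))
      traces[, e] <- traces[, e] + zero_phase_filter(bf$b, bf$a, noise[, e])
  }

  soma <- do.call(rbind, lapply(units, function(u)
    if (is.null(u$soma_position)) NULL
    else data.frame(x = u$soma_position[1], y = u$soma_position[2])))
  if (is.null(soma)) soma <- data.frame(x = numeric(0), y = numeric(0))

  structure(list(layout = layout, sampling_rate = sampling_rate,
                 traces = traces, units = units, spike_times = trains,
                 soma_table = soma, noise_sd = noise_sd,
                 duration = duration),
            class = "eap_recording")
}

#' @export
print.eap_recording <- function(x, ...) {
  cat(sprintf("Synthetic HDMEA recording: %d electrodes, %.3g s at %g kHz, %d units, noise sd %g uV\n",
              ncol(x$traces), x$duration, x$sampling_rate / 1000,
              length(x$units), x$noise_sd))
  invisible(x)
}
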