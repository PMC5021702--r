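# Shared fixture builders (all data generated in code).

# Gaussian trough of given width parameter (us) on a regular grid
gauss_trough <- function(sigma_us, dt_us, half_window_us = 1250,
                         depth = 1, center_us = 0) {
  t <- seq(-half_window_us, half_window_us, by = dt_us)
  -depth * exp(-(t - center_us)^2 / (2 * sigma_us^2))
}

# negative trough at 0 plus a positive lobe at `offset_us`
two_lobe <- function(offset_us, dt_us, sigma_neg = 55.2, sigma_pos = 110,
                     pos_amp = 0.4, half_window_us = 1250) {
  t <- seq(-half_window_us, half_window_us, by = dt_us)
  -exp(-t^2 / (2 * sigma_neg^2)) +
    pos_amp * exp(-(t - offset_us)^2 / (2 * sigma_pos^2))
}

# insert a waveform into a trace, trough landing at each position (samples)
insert_spikes <- function(trace, waveform, positions, trough_index) {
  nw <- length(waveform)
  for (p in positions) {
    a <- p - trough_index + 1L
    b <- a + nw - 1L
    if (a < 1 || b > length(trace)) next
    trace[a:b] <- trace[a:b] + waveform
  }
  trace
}

# a single-unit recording block on a 3x3 patch (the population-study
# geometry) for reuse across tests
single_unit_block <- function(kind = "somatic_type1", duration = 60,
                              noise_sd = 10, seed = 42,
                              soma_offset = if (grepl("^somatic", kind))
                                c(0, 0) else c(150, 0)) {
  lay <- make_layout(3, 3)
  center <- which.min((lay$x - mean(lay$x))^2 + (lay$y - mean(lay$y))^2)
  origin <- c(lay$x[center], lay$y[center])
  u <- make_unit(1, kind, origin, soma_position = origin + soma_offset)
  st <- make_spike_train(duration, 1, 100, 5, seed = seed)
  rec <- render_recording(lay, list(u), list(st), noise_sd = noise_sd,
                          duration = duration, seed = seed + 1L)
  list(recording = rec, unit = u, spike_times = st, origin = origin,
       layout = lay)
}
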