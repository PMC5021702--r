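#' Default analysis configuration
#'
#' All tunable parameters of the analysis chain with their standard
#' values: 20 kHz acquisition, 320 kHz oversampling, 500-3,000 Hz
#' detection band, 5-sigma threshold, 0.8 ms blanking, 2.5 ms snippet
#' window, 0.2 Hz activity cut, screening at 100 uV / RSTD 1 / 100
#' spikes, 50 um soma-distance rule, and cFR decay constant 0.1 s.
#'
#' @param ... Name-value overrides of any field.
#' @return Named list of class `eap_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    sampling_rate = 20000,
    oversample_rate = 320000,
    band_low = 500, band_high = 3000,
    threshold_k = 5,
    blank = 0.8e-3,
    window = 2.5e-3,
    activity_min = 0.2,
    screen_min_amplitude = 100,
    screen_max_rstd = 1,
    screen_min_spikes = 100,
    soma_distance = 50,
    tau = 0.1,
    n_pc = 10,
    kmeans_k = 8,
    agg_criterion = 0.001,
    rpv_refractory = 1.5e-3,
    rpv_max = 0.01,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("eap_config", "list")
  cfg
}

# nearest `k` layout neighbours of an electrode column index (inclusive)
trio_columns <- function(layout, col) {
  d <- layout_distances(layout, layout$x[col], layout$y[col])
  order(d)[1:3]
}

#' Analyse one recording block
#'
#' Runs the full analysis chain on one block: band-pass filtering,
#' per-electrode threshold detection, activity map, spike sorting on the
#' three most suitable neighbouring electrodes, a spike-triggered-average
#' footprint from the wideband traces, waveform features of the
#' representative electrode, screening, template classification, the
#' soma-distance label, and per-feature spike-shape-adaptation fits.
#' One footprint (the accepted unit with most spikes) is extracted per
#' block.
#'
#' @param recording An `eap_recording`, or a list with `traces`, `layout`,
#'   `sampling_rate` (e.g. from [read_traces()]).
#' @param config An [default_config()] list.
#' @param templates Template set (default [default_templates()] at the
#'   configured oversample rate).
#' @param soma_table data.frame of soma positions (`x`, `y`, um); default
#'   taken from the recording if present, else empty.
#' @return List of class `eap_block_result`: `activity`, `trio`
#'   (electrode ids used for sorting), `n_events`, `units` (all sorted),
#'   `unit` (the accepted unit, or NULL), `footprint`, `features`,
#'   `screened` (logical), `classification`, `distance_label`,
#'   `adaptation` (named list of `adaptation_fit`s), `log` (stage
#'   counts).
#' @export
analyze_block <- function(recording, config = default_config(),
                          templates = NULL, soma_table = NULL) {
  fs <- recording$sampling_rate
  layout <- recording$layout
  raw <- as.matrix(recording$traces)
  if (is.null(soma_table))
    soma_table <- if (!is.null(recording$soma_table)) recording$soma_table
                  else data.frame(x = numeric(0), y = numeric(0))
  if (is.null(templates))
    templates <- default_templates(config$oversample_rate, config$window * 1e3)

  duration <- nrow(raw) / fs
  filt <- apply(raw, 2, bandpass, sampling_rate = fs,
                low = config$band_low, high = config$band_high)

  events <- lapply(seq_len(ncol(filt)), function(e)
    detect_events(filt[, e], fs, k_threshold = config$threshold_k,
                  blank = config$blank, window = config$window))
  counts <- vapply(events, nrow, integer(1))
  act <- activity_map(stats::setNames(counts, layout$electrode_id), duration,
                      min_rate = config$activity_min)
  log <- list(n_electrodes = ncol(raw), n_events_total = sum(counts),
              n_active_electrodes = sum(act$active))

  empty <- function(reason) {
    log$drop_reason <- reason
    structure(list(activity = act, trio = integer(0),
                   n_events = sum(counts), units = list(), unit = NULL,
                   footprint = NULL, features = NULL, screened = FALSE,
                   classification = NULL, distance_label = NA_character_,
                   adaptation = list(), log = log),
              class = "eap_block_result")
  }
  if (!any(act$active)) return(empty("no active electrodes"))

  lead_col <- which.max(act$firing_rate_hz)
  trio <- trio_columns(layout, lead_col)
  stacked <- align_and_stack(events[trio], filt[, trio, drop = FALSE], fs,
                             window = config$window)
  log$n_stacked_events <- nrow(stacked)
  if (nrow(stacked) < 2) return(empty("too few events on the sorting trio"))

  units <- cluster_events(stacked, n_pc = config$n_pc,
                          kmeans_k = config$kmeans_k,
                          agg_criterion = config$agg_criterion,
                          refractory = config$rpv_refractory)
  kept <- accept_units(units, max_rpv = config$rpv_max,
                       min_spikes = config$screen_min_spikes)
  log$n_units <- length(units); log$n_units_accepted <- length(kept)
  if (length(kept) == 0) return(empty("no unit passed acceptance"))
  unit <- kept[[which.max(vapply(kept, `[[`, 0, "n_spikes"))]]

  fp <- footprint(unit$spike_times, raw, fs,
                  electrode_ids = layout$electrode_id,
                  window = config$window,
                  oversample_rate = config$oversample_rate)
  rep_col <- fp$representative_column
  sta <- fp$sta[, rep_col]
  dt_us <- 1e6 / fp$sampling_rate

  # contributing wideband snippets at the representative electrode
  snips <- spike_snippets(raw[, rep_col], unit$spike_times, fs,
                          config$window)
  feats <- waveform_features(sta, dt_us, snippets = snips$snippets,
                             n_spikes = unit$n_spikes)
  screened <- screen_features(feats,
                              min_amplitude_uV = config$screen_min_amplitude,
                              max_rstd = config$screen_max_rstd,
                              min_spikes = config$screen_min_spikes)
  cls <- if (screened) match_template(sta, templates) else NULL
  dlab <- distance_label(c(layout$x[rep_col], layout$y[rep_col]),
                         soma_table, config$soma_distance)

  adaptation <- list()
  if (screened) {
    cfr <- continuous_firing_rate(snips$times, config$tau)
    pf <- per_spike_features(snips$snippets, fs, config$oversample_rate)
    adaptation <- fit_all_adaptation(pf, cfr)
  }

  structure(list(activity = act, trio = layout$electrode_id[trio],
                 n_events = sum(counts), units = units, unit = unit,
                 footprint = fp, features = feats, screened = screened,
                 classification = cls, distance_label = dlab,
                 adaptation = adaptation, log = log),
            class = "eap_block_result")
}

# fixed-window snippets around spike times (drops edge-truncated spikes)
spike_snippets <- function(trace, spike_times, sampling_rate, window) {
  n <- length(trace)
  n_win <- round(window * sampling_rate)
  pre <- floor(n_win / 2); post <- n_win - pre - 1L
  centers <- round(spike_times * sampling_rate) + 1L
  ok <- centers - pre >= 1L & centers + post <= n
  snips <- t(vapply(centers[ok], function(p) trace[(p - pre):(p + post)],
                    numeric(n_win)))
  list(snippets = snips, times = spike_times[ok])
}

# per-spike shape features from oversampled individual snippets
per_spike_features <- function(snippets, sampling_rate, oversample_rate) {
  dt_us <- 1e6 / oversample_rate
  out <- t(apply(snippets, 1, function(s) {
    ov <- oversample(s, sampling_rate, oversample_rate)
    amp <- min(ov)
    hw <- tryCatch(sta_half_width(ov, dt_us), error = function(e) NA_real_)
    tp <- if (amp < 0) sta_trough_peak_width(ov, dt_us) else NA_real_
    c(amplitude = amp, half_width = hw, trough_peak = tp)
  }))
  as.data.frame(out)
}

# adaptation fits for the three shape features; amplitude fitted on its
# magnitude so shrinking spikes give negative AR
fit_all_adaptation <- function(per_spike, cfr) {
  feats <- list(amplitude = abs(per_spike$amplitude),
                half_width = per_spike$half_width,
                trough_peak_width = per_spike$trough_peak)
  out <- list()
  for (nm in names(feats)) {
    y <- feats[[nm]]
    if (sum(is.finite(y)) < 10) next
    fit <- tryCatch(fit_adaptation(y, cfr$cfr_hz, feature_name = nm),
                    error = function(e) NULL)
    if (!is.null(fit)) out[[nm]] <- fit
  }
  out
}

#' Run the full pipeline over one or more recording blocks
#'
#' Drives the whole chain (detect, activity map, sort, footprint,
#' features, screen, template match, distance label, adaptation, group
#' comparison) over a set of recording blocks and writes all stage CSVs
#' plus a summary to `output_dir`. Deterministic given `config$seed`.
#'
#' @param inputs List of `eap_recording` objects, or character paths to
#'   [write_traces()] files.
#' @param output_dir Output directory (created). `NULL` skips writing.
#' @param config [default_config()] list.
#' @param templates Optional template set (default canonical set).
#' @param soma_table Optional soma table applied to all blocks lacking one.
#' @return List of class `eap_report`: `blocks` (per-block results),
#'   `records` (one data.frame row per block: features, screening,
#'   classification, labels, AR values), `summary` (population fractions),
#'   `comparison` (somatic-vs-neuritic AR tests, when computable).
#' @export
run_pipeline <- function(inputs, output_dir = NULL,
                         config = default_config(), templates = NULL,
                         soma_table = NULL) {
  set.seed(config$seed)
  if (is.null(templates))
    templates <- default_templates(config$oversample_rate, config$window * 1e3)
  if (!is.list(inputs) || inherits(inputs, "eap_recording"))
    inputs <- list(inputs)

  manifest <- character(0)
  blocks <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    rec <- inputs[[i]]
    if (is.character(rec)) rec <- read_traces(rec)
    blocks[[i]] <- tryCatch(
      analyze_block(rec, config, templates, soma_table),
      error = function(e)
        stop("pipeline stage failure in block ", i, ": ",
             conditionMessage(e)))
    manifest <- c(manifest, sprintf("block %d analysed", i))
  }

  records <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    f <- b$features
    ar <- function(nm) if (!is.null(b$adaptation[[nm]]))
      b$adaptation[[nm]]$ar_percent else NA_real_
    data.frame(
      block = i,
      n_events = b$n_events,
      n_spikes = if (is.null(b$unit)) 0L else b$unit$n_spikes,
      amplitude_uV = if (is.null(f)) NA_real_ else f$amplitude_uV,
      half_width_us = if (is.null(f)) NA_real_ else f$half_width_us,
      trough_peak_width_us = if (is.null(f)) NA_real_ else
        f$trough_peak_width_us,
      rstd = if (is.null(f)) NA_real_ else f$rstd,
      screened = b$screened,
      assigned_type = if (is.null(b$classification)) NA_integer_ else
        b$classification$assigned_type,
      source_class = if (is.null(b$classification)) NA_character_ else
        b$classification$source_class,
      distance_label = b$distance_label,
      ar_amplitude = ar("amplitude"),
      ar_half_width = ar("half_width"),
      ar_trough_peak_width = ar("trough_peak_width"))
  }))

  screened <- records[records$screened & !is.na(records$assigned_type), ,
                      drop = FALSE]
  summary <- if (nrow(screened) > 0)
    population_summary(data.frame(assigned_type = screened$assigned_type))
  else NULL

  comparison <- NULL
  if (nrow(screened) > 1) {
    ok <- is.finite(screened$ar_amplitude)
    if (length(unique(screened$source_class[ok])) == 2 &&
        all(table(screened$source_class[ok]) >= 3)) {
      comparison <- compare_groups(screened$ar_amplitude[ok],
                                   screened$source_class[ok])
    }
  }

  out <- structure(list(blocks = blocks, records = records,
                        summary = summary, comparison = comparison,
                        config = config),
                   class = "eap_report")
  if (!is.null(output_dir)) write_report(out, output_dir, manifest)
  out
}

write_report <- function(report, dir, manifest) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  act <- do.call(rbind, lapply(seq_along(report$blocks), function(i)
    cbind(block = i, report$blocks[[i]]$activity)))
  wcsv(act, "activity.csv"); manifest <- c(manifest, "activity.csv")
  units <- do.call(rbind, lapply(seq_along(report$blocks), function(i) {
    b <- report$blocks[[i]]
    if (length(b$units) == 0) return(NULL)
    do.call(rbind, lapply(b$units, function(u)
      data.frame(block = i, unit_id = u$unit_id, n_spikes = u$n_spikes,
                 rpv_fraction = u$rpv_fraction)))
  }))
  if (!is.null(units)) { wcsv(units, "units.csv")
                         manifest <- c(manifest, "units.csv") }
  wcsv(report$records, "records.csv"); manifest <- c(manifest, "records.csv")
  if (!is.null(report$summary)) {
    wcsv(report$summary$pooled, "population.csv")
    manifest <- c(manifest, "population.csv")
  }
  if (!is.null(report$comparison)) {
    wcsv(report$comparison$tests, "comparison.csv")
    manifest <- c(manifest, "comparison.csv")
  }
  writeLines(manifest, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @export
print.eap_report <- function(x, ...) {
  cat(sprintf("EAP pipeline report: %d blocks, %d screened records\n",
              length(x$blocks), sum(x$records$screened)))
  if (!is.null(x$summary))
    cat(sprintf("  somatic (types 1-2) fraction: %.1f%%\n",
                100 * x$summary$somatic_fraction))
  if (!is.null(x$comparison))
    cat(sprintf("  somatic vs neuritic amplitude-AR: p = %.3g\n",
                x$comparison$tests$p_two_tailed[1]))
  invisible(x)
}
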