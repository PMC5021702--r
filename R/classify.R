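#' Screening constraints for averaged spikes
#'
#' A record enters template classification only if its averaged spike has
#' a negative peak amplitude of at least 100 uV, an RSTD lower than 1, and
#' more than 100 spikes. The amplitude bound is inclusive; the RSTD and
#' spike-count bounds are strict.
#'
#' @param features One-row `eap_features` data.frame (or anything with
#'   `amplitude_uV`, `rstd`, `n_spikes`).
#' @param min_amplitude_uV,max_rstd,min_spikes Screening thresholds
#'   (defaults 100 uV, 1, 100).
#' @return Logical: does the record pass?
#' @export
screen_features <- function(features, min_amplitude_uV = 100,
                            max_rstd = 1, min_spikes = 100) {
  isTRUE(abs(features$amplitude_uV) >= min_amplitude_uV &&
         features$rstd < max_rstd &&
         features$n_spikes > min_spikes)
}

#' Assign an averaged spike to a template type by cross-correlation
#'
#' The waveform and the four templates are peak-to-peak normalized and
#' trough-aligned; for every template the normalized cross-correlation
#' (cosine similarity) is maximized over lags within `max_lag_s`, and the
#' spike is assigned to the template with the highest score. Ties go to
#' the lower type index with a warning.
#'
#' @param waveform Averaged spike (uV), sampled at the templates' rate.
#' @param templates An `eap_templates` object (see [default_templates()]).
#' @param max_lag_s Lag search half-window, seconds (default 0.25 ms).
#' @return `eap_classification` data.frame row: `assigned_type` (1-4),
#'   `score_1`..`score_4` (in [-1, 1]), `source_class` ("somatic" for
#'   types 1-2, "neuritic" for 3-4).
#' @export
match_template <- function(waveform, templates, max_lag_s = 0.25e-3) {
  fs <- attr(templates, "sampling_rate")
  w <- as.numeric(waveform)
  if (max(w) - min(w) <= 0) stop("flat waveform cannot be classified")
  w <- w / (max(w) - min(w))
  nt <- nrow(templates)
  # put the waveform on the template time base, trough-centred
  if (length(w) != nt) {
    if (length(w) > nt) stop("waveform longer than the template time base")
    pad <- numeric(nt); pad[seq_along(w)] <- w
    w <- pad
  }
  w <- center_on_trough(w, floor(nt / 2) + 1L)
  max_lag <- round(max_lag_s * fs)
  scores <- vapply(1:4, function(k) {
    tpl <- unclass(templates)[, k]
    best <- -Inf
    for (lag in -max_lag:max_lag) {
      ws <- shift_pad(w, lag)
      s <- sum(ws * tpl) / sqrt(sum(ws^2) * sum(tpl^2))
      if (is.finite(s) && s > best) best <- s
    }
    best
  }, numeric(1))
  best <- max(scores)
  winners <- which(scores >= best - 1e-12)
  if (length(winners) > 1)
    warning("template score tie; assigning the lower type index")
  assigned <- min(winners)
  out <- data.frame(assigned_type = assigned,
                    score_1 = scores[1], score_2 = scores[2],
                    score_3 = scores[3], score_4 = scores[4],
                    source_class = if (assigned <= 2) "somatic" else "neuritic")
  class(out) <- c("eap_classification", "data.frame")
  out
}

# circularly-safe integer shift with zero padding
shift_pad <- function(x, lag) {
  n <- length(x)
  out <- numeric(n)
  if (lag >= 0) out[(1 + lag):n] <- x[1:(n - lag)]
  else out[1:(n + lag)] <- x[(1 - lag):n]
  out
}

# translate a waveform so its global minimum sits at `target_index`
center_on_trough <- function(w, target_index) {
  shift_pad(w, target_index - which.min(w))
}

#' Somatic/neuritic label from soma distance
#'
#' Labels a recording site by the distance from its representative
#' electrode to the nearest soma: somatic when strictly less than
#' `max_distance_um` (default 50 um), neuritic otherwise. With no somata
#' in the table the label is neuritic.
#'
#' @param position Numeric `c(x, y)` of the representative electrode, um.
#' @param soma_table data.frame with columns `x`, `y` (um); may be empty.
#' @param max_distance_um Somatic distance bound, um (default 50, strict).
#' @return `"somatic"` or `"neuritic"`.
#' @export
distance_label <- function(position, soma_table, max_distance_um = 50) {
  if (is.null(soma_table) || nrow(soma_table) == 0) return("neuritic")
  d <- sqrt((soma_table$x - position[1])^2 + (soma_table$y - position[2])^2)
  if (min(d) < max_distance_um) "somatic" else "neuritic"
}

#' Per-type population summary
#'
#' Counts and fractions of records assigned to each template type, pooled
#' and optionally per experiment/group, plus the somatic (types 1-2)
#' fraction.
#'
#' @param results data.frame with column `assigned_type` (and optionally
#'   `source_class`), e.g. rbind-ed [match_template()] rows.
#' @param group Optional grouping vector (experiment ids).
#' @return List with `pooled` (data.frame: type, count, fraction),
#'   `somatic_fraction`, and `per_group` when `group` is given.
#' @export
population_summary <- function(results, group = NULL) {
  if (is.null(results) || nrow(results) == 0) stop("no classification results")
  tab <- function(types) {
    counts <- vapply(1:4, function(k) sum(types == k), integer(1))
    data.frame(type = 1:4, count = counts,
               fraction = counts / length(types))
  }
  pooled <- tab(results$assigned_type)
  out <- list(pooled = pooled,
              somatic_fraction = sum(pooled$fraction[1:2]))
  if (!is.null(group)) {
    out$per_group <- lapply(split(results$assigned_type, group), tab)
  }
  out
}
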