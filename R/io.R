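#' Trace container I/O
#'
#' A minimal single-file container for multichannel voltage traces with
#' electrode geometry: a versioned plain-text header (magic line,
#' `n_electrodes`, `n_samples`, `sampling_rate_hz`, `scale_uV`, then one
#' `electrode_id x_um y_um` line per electrode, then `DATA`), followed by
#' the samples as little-endian float64 in electrode-major order.
#' Round-trips are bit-exact.
#'
#' @param recording An `eap_recording` (or a list with `traces`, `layout`,
#'   `sampling_rate`).
#' @param path File path.
#' @return `read_traces` returns a list: `traces` (samples x electrodes),
#'   `layout`, `sampling_rate`.
#' @export
write_traces <- function(recording, path) {
  traces <- recording$traces
  layout <- recording$layout
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("EAPTRACE v1",
           sprintf("n_electrodes %d", ncol(traces)),
           sprintf("n_samples %d", nrow(traces)),
           sprintf("sampling_rate_hz %.9g", recording$sampling_rate),
           "scale_uV 1",
           sprintf("%d %.9g %.9g", layout$electrode_id, layout$x, layout$y),
           "DATA")
  writeLines(hdr, con)
  writeBin(as.numeric(traces), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "EAPTRACE v1"))
    stop("not an EAPTRACE v1 file (bad magic line)")
  get_field <- function(name) {
    ln <- readLines(con, n = 1L)
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    if (length(parts) != 2 || parts[1] != name)
      stop("malformed header: expected field '", name, "', got '", ln, "'")
    as.numeric(parts[2])
  }
  n_el <- get_field("n_electrodes")
  n_s <- get_field("n_samples")
  fs <- get_field("sampling_rate_hz")
  scale <- get_field("scale_uV")
  if (!is.finite(n_el) || n_el < 1) stop("malformed header: n_electrodes")
  if (!is.finite(n_s) || n_s < 1) stop("malformed header: n_samples")
  if (!is.finite(fs) || fs <= 0) stop("malformed header: sampling_rate_hz")
  el_lines <- readLines(con, n = n_el)
  if (length(el_lines) != n_el) stop("truncated header: electrode table")
  el_parts <- strsplit(el_lines, " ", fixed = TRUE)
  if (any(lengths(el_parts) != 3)) stop("malformed header: electrode table")
  el <- data.frame(
    electrode_id = as.integer(vapply(el_parts, `[`, "", 1)),
    x = as.numeric(vapply(el_parts, `[`, "", 2)),
    y = as.numeric(vapply(el_parts, `[`, "", 3)))
  data_line <- readLines(con, n = 1L)
  if (!identical(data_line, "DATA")) stop("malformed header: missing DATA line")
  vals <- readBin(con, "double", n = n_el * n_s, size = 8, endian = "little")
  if (length(vals) != n_el * n_s)
    stop("truncated trace file: expected ", n_el * n_s, " samples, got ",
         length(vals))
  layout <- el
  class(layout) <- c("eap_layout", "data.frame")
  list(traces = matrix(vals * scale, n_s, n_el), layout = layout,
       sampling_rate = fs)
}

#' Write ground-truth tables of a synthetic recording
#'
#' `units.csv` (unit_id, kind, x_um, y_um, soma_x_um, soma_y_um) and
#' `spikes.csv` (unit_id, time_s).
#'
#' @param recording An `eap_recording`.
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units <- do.call(rbind, lapply(recording$units, function(u)
    data.frame(unit_id = u$unit_id, kind = u$kind,
               x_um = u$origin[1], y_um = u$origin[2],
               soma_x_um = if (is.null(u$soma_position)) NA_real_
                           else u$soma_position[1],
               soma_y_um = if (is.null(u$soma_position)) NA_real_
                           else u$soma_position[2])))
  utils::write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  spikes <- do.call(rbind, lapply(seq_along(recording$units), function(k)
    if (length(recording$spike_times[[k]]) == 0) NULL else
    data.frame(unit_id = recording$units[[k]]$unit_id,
               time_s = sprintf("%.9f", recording$spike_times[[k]]))))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = integer(0), time_s = character(0))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  invisible(dir)
}
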