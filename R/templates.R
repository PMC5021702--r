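#' @keywords internal
template_kinds <- c("somatic_type1", "somatic_type2",
                    "neuritic_type3", "neuritic_type4")

# FWHM of a Gaussian = 2*sigma*sqrt(2*log(2)); invert to hit a target
# half-width with a Gaussian trough.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Per-kind default lobe geometry (all times in us, amplitudes relative to
# the unit-depth negative trough). Lobe offsets are large relative to lobe
# widths so the closed-form feature values of each lobe survive summation.
#
# somatic (broad): trough half-width 250 us; type 2 adds a positive peak
#   900 us after the trough. neuritic (narrow): half-width 130 us; positive
#   peaks 420 us from the trough; type 3 has its larger positive peak before
#   the trough, type 4 is symmetric.
template_defaults <- function(kind) {
  switch(kind,
    somatic_type1 = list(
      neg_sigma = fwhm_to_sigma(250),
      lobes = data.frame(offset = numeric(0), amp = numeric(0),
                         sigma = numeric(0))),
    somatic_type2 = list(
      neg_sigma = fwhm_to_sigma(250),
      lobes = data.frame(offset = 900, amp = 0.30, sigma = 200)),
    neuritic_type3 = list(
      neg_sigma = fwhm_to_sigma(130),
      lobes = data.frame(offset = c(-420, 420), amp = c(0.50, 0.25),
                         sigma = c(110, 110))),
    neuritic_type4 = list(
      neg_sigma = fwhm_to_sigma(130),
      lobes = data.frame(offset = c(-420, 420), amp = c(0.35, 0.35),
                         sigma = c(110, 110))),
    stop("unknown waveform kind: ", kind)
  )
}

#' Canonical extracellular waveform templates
#'
#' Generates one of the four canonical extracellular action-potential
#' shapes as a parametric sum of Gaussian lobes: one unit-depth negative
#' lobe (the trough) plus zero to two positive lobes. Types 1-2 are the
#' wide somatic shapes (monophasic / biphasic, half-width 250 us,
#' trough-peak width 900 us for type 2); types 3-4 are the narrow
#' triphasic neuritic shapes (half-width 130 us, trough-peak width 420 us;
#' type 3 has its larger positive peak before the trough, type 4 is
#' symmetric).
#'
#' @param kind One of `"somatic_type1"`, `"somatic_type2"`,
#'   `"neuritic_type3"`, `"neuritic_type4"`.
#' @param sampling_rate Samples per second; must be >= 20000.
#' @param window_ms Window length in ms (default 2.5); must be >= 2.5.
#' @param params Optional list overriding the per-kind defaults:
#'   `neg_sigma` (us) and `lobes` (data.frame offset/amp/sigma in us).
#' @return Numeric voltage vector (trough depth -1, dimensionless; scale
#'   by a unit's amplitude to get uV) with attributes `sampling_rate` and
#'   `trough_index` (trough-centred time base).
#' @export
make_template_waveform <- function(kind, sampling_rate = 320000,
                                   window_ms = 2.5, params = NULL) {
  kind <- match.arg(kind, template_kinds)
  if (!is.numeric(sampling_rate) || sampling_rate < 20000)
    stop("sampling_rate must be >= 20 kHz")
  if (window_ms < 2.5) stop("window must cover at least 2.5 ms")
  p <- template_defaults(kind)
  if (!is.null(params)) p[names(params)] <- params

  n <- round(window_ms * 1e-3 * sampling_rate)
  i0 <- floor(n / 2) + 1L                     # trough sample
  t_us <- (seq_len(n) - i0) / sampling_rate * 1e6

  w <- -exp(-t_us^2 / (2 * p$neg_sigma^2))
  if (nrow(p$lobes) > 0) {
    for (j in seq_len(nrow(p$lobes))) {
      w <- w + p$lobes$amp[j] *
        exp(-(t_us - p$lobes$offset[j])^2 / (2 * p$lobes$sigma[j]^2))
    }
  }
  attr(w, "sampling_rate") <- sampling_rate
  attr(w, "trough_index") <- i0
  w
}

#' Default template set for classification
#'
#' The four canonical waveforms on a common trough-centred time base, each
#' peak-to-peak normalized, as used for cross-correlation template
#' matching. A measured template set read with [read_templates()] can be
#' substituted anywhere this one is accepted.
#'
#' @inheritParams make_template_waveform
#' @return An `eap_templates` object: an n x 4 numeric matrix (columns
#'   `type1`..`type4`) with attribute `sampling_rate`.
#' @export
default_templates <- function(sampling_rate = 320000, window_ms = 2.5) {
  m <- sapply(template_kinds, function(k)
    make_template_waveform(k, sampling_rate, window_ms))
  m <- apply(m, 2, function(w) w / (max(w) - min(w)))
  colnames(m) <- paste0("type", 1:4)
  attr(m, "sampling_rate") <- sampling_rate
  class(m) <- c("eap_templates", class(m))
  m
}

#' Read / write a template set as CSV
#'
#' Plain four-column numeric CSV; the sample period in microseconds is
#' carried in a comment line `# sample_period_us: <x>` above the header.
#'
#' @param templates An `eap_templates` matrix.
#' @param path File path.
#' @return `read_templates` returns an `eap_templates` object.
#' @export
write_templates <- function(templates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_period_us: %.9g",
                     1e6 / attr(templates, "sampling_rate")), con)
  utils::write.csv(as.data.frame(unclass(templates)[, , drop = FALSE]),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("# sample_period_us: *([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("template file missing '# sample_period_us:' line")
  dt_us <- as.numeric(m[2])
  d <- utils::read.csv(path, comment.char = "#")
  if (ncol(d) != 4) stop("template file must have exactly 4 waveform columns")
  mat <- as.matrix(d)
  colnames(mat) <- paste0("type", 1:4)
  attr(mat, "sampling_rate") <- 1e6 / dt_us
  class(mat) <- c("eap_templates", class(mat))
  mat
}
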