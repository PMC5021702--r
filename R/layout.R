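#' Hexagonal electrode layout
#'
#' Builds a hexagonally packed electrode grid of the kind used by CMOS
#' high-density microelectrode arrays: rows are spaced `pitch * sqrt(3)/2`
#' apart and alternate rows are offset by half a pitch, so every electrode's
#' nearest neighbours sit exactly `pitch` micrometres away.
#'
#' @param n_rows,n_cols Grid extents (>= 1).
#' @param pitch Centre-to-centre electrode distance in micrometres.
#'   Default 17.8, the pitch of the 11,011-electrode arrays this package
#'   emulates.
#' @return An object of class `eap_layout`: a data.frame with columns
#'   `electrode_id` (0-based, contiguous), `x`, `y` (um), and attributes
#'   `pitch`, `n_rows`, `n_cols`.
#' @examples
#' lay <- make_layout(12, 6)
#' nrow(lay)       # 72 electrodes
#' @export
make_layout <- function(n_rows, n_cols, pitch = 17.8) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (!is.numeric(pitch) || length(pitch) != 1L || is.na(pitch) || pitch <= 0)
    stop("pitch must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x <- col * pitch + ifelse(row %% 2L == 1L, pitch / 2, 0)
  y <- row * pitch * sqrt(3) / 2

  out <- data.frame(
    electrode_id = seq_along(x) - 1L,
    x = x, y = y
  )
  attr(out, "pitch") <- pitch
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  class(out) <- c("eap_layout", "data.frame")
  out
}

#' @export
print.eap_layout <- function(x, ...) {
  cat(sprintf("Hexagonal electrode layout: %d electrodes (%d rows x %d cols), pitch %.4g um\n",
              nrow(x), attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "pitch")))
  invisible(x)
}

# Euclidean distances from a point to every electrode of a layout (um).
layout_distances <- function(layout, x, y) {
  sqrt((layout$x - x)^2 + (layout$y - y)^2)
}
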