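#' Electrode layout of a high-density multi-electrode array
#'
#' Describes the rectangular electrode grid of an HD-MEA chip.  The default
#' matches the 4096-channel active-pixel-sensor array used for cortical slice
#' work: 64 x 64 electrodes at a 42 um pitch (active area about 7.22 mm^2,
#' about 567 electrodes per mm^2).
#'
#' Coordinate convention, used everywhere in the package: rows increase
#' downward, columns increase rightward, indices are 1-based.  Physical
#' positions are `x = (col - 1) * pitch`, `y = (row - 1) * pitch` (in um).
#' Angles quoted in analyses are measured counter-clockwise in the flipped-y
#' frame (y pointing up), i.e. `theta = atan2(-(row - r0), col - c0)`.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param pitch electrode pitch in micrometres (> 0).
#' @return An object of class `electrode_layout` with fields `n_rows`,
#'   `n_cols`, `n_channels`, `pitch`, and per-channel `row`, `col`, `x_um`,
#'   `y_um` vectors.  Channels are numbered column-major over the grid
#'   (channel = row + (col - 1) * n_rows), matching `as.vector()` on a frame
#'   matrix.
#' @examples
#' lay <- electrode_layout()
#' lay$n_channels        # 4096
#' @export
electrode_layout <- function(n_rows = 64L, n_cols = 64L, pitch = 42) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows), times = n_cols)
  col <- rep(seq_len(n_cols), each = n_rows)
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      n_channels = n_rows * n_cols,
      pitch = pitch,
      row = row, col = col,
      x_um = (col - 1) * pitch,
      y_um = (row - 1) * pitch
    ),
    class = "electrode_layout"
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d x %d electrodes, pitch %g um\n",
              x$n_rows, x$n_cols, x$pitch))
  invisible(x)
}

#' Pairwise electrode distances
#'
#' @param layout an [electrode_layout()].
#' @param channels optional integer subset of channels.
#' @return A dense symmetric matrix of Euclidean distances in um.
#' @export
layout_distances <- function(layout, channels = NULL) {
  stopifnot(inherits(layout, "electrode_layout"))
  x <- layout$x_um; y <- layout$y_um
  if (!is.null(channels)) { x <- x[channels]; y <- y[channels] }
  as.matrix(stats::dist(cbind(x, y)))
}

## nearest channel to a fractional (row, col) grid position
nearest_channel <- function(layout, row, col) {
  d2 <- (layout$row - row)^2 + (layout$col - col)^2
  which.min(d2)
}
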