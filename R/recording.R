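#' Construct a voltage recording
#'
#' Container for extracellular voltage: a channels x time matrix in
#' microvolts bound to an [electrode_layout()] and a sampling rate.
#'
#' @param voltage numeric matrix, channels x time, in uV.  Channel ordering
#'   is column-major over the grid (see [electrode_layout()]).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param layout an [electrode_layout()]; channel count must match.
#' @param provenance character tags describing processing history
#'   (`"raw"`, `"filtered"`, `"cleaned"`, ...).
#' @return An object of class `voltage_recording`.
#' @export
voltage_recording <- function(voltage, sampling_rate, layout,
                              provenance = "raw") {
  stopifnot(is.matrix(voltage), inherits(layout, "electrode_layout"))
  if (nrow(voltage) != layout$n_channels)
    stop("channel count (", nrow(voltage), ") does not match layout (",
         layout$n_channels, ")")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(
    list(voltage = voltage, sampling_rate = sampling_rate,
         layout = layout, provenance = provenance),
    class = "voltage_recording"
  )
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf(
    "<voltage_recording> %d channels x %d samples @ %g Hz (%.2f s) [%s]\n",
    nrow(x$voltage), ncol(x$voltage), x$sampling_rate,
    ncol(x$voltage) / x$sampling_rate, paste(x$provenance, collapse = " > ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [voltage_recording()].
#' @return duration in s.
#' @export
recording_duration <- function(rec) {
  ncol(rec$voltage) / rec$sampling_rate
}

#' Construct a snapshot stack
#'
#' Time-ordered sequence of full-array activity frames ("snapshots"), the
#' representation all wave and complexity analyses operate on.  Stored as a
#' 3-D array frames-last: `n_rows x n_cols x n_frames`.
#'
#' @param frames 3-D numeric array (rows x cols x frames) or a list of equal
#'   sized matrices.
#' @param frame_interval frame spacing in seconds (default 1 ms).
#' @param window source window `c(start_s, end_s)` or `NULL`.
#' @return An object of class `snapshot_stack`.
#' @export
snapshot_stack <- function(frames, frame_interval = 0.001, window = NULL) {
  if (is.list(frames)) {
    dims <- dim(frames[[1]])
    frames <- array(unlist(frames), dim = c(dims, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, frame_interval > 0)
  structure(
    list(frames = frames, frame_interval = frame_interval, window = window),
    class = "snapshot_stack"
  )
}

#' @export
print.snapshot_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<snapshot_stack> %d frames of %d x %d @ %g ms\n",
              d[3], d[1], d[2], 1000 * x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [snapshot_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack a [snapshot_stack()].
#' @param i frame index.
#' @return rows x cols matrix.
#' @export
get_frame <- function(stack, i) stack$frames[, , i, drop = TRUE]

#' Flatten a stack to a channels x frames matrix
#'
#' Channels are ordered column-major over the grid, matching
#' [electrode_layout()] channel numbering.
#'
#' @param stack a [snapshot_stack()].
#' @return matrix with one row per electrode, one column per frame.
#' @export
as_channel_matrix <- function(stack) {
  d <- dim(stack$frames)
  matrix(stack$frames, nrow = d[1] * d[2], ncol = d[3])
}

#' Subset frames of a stack
#' @param stack a [snapshot_stack()].
#' @param idx frame indices (kept in the given order).
#' @return a new [snapshot_stack()].
#' @export
subset_frames <- function(stack, idx) {
  snapshot_stack(stack$frames[, , idx, drop = FALSE],
                 frame_interval = stack$frame_interval,
                 window = stack$window)
}
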