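#' Extract 1-ms snapshots from a recording
#'
#' Converts a (channels x time) voltage matrix into a time-ordered stack of
#' full-array frames.  Each frame is the per-channel mean over its time bin
#' (bin-averaging rather than decimation, to avoid aliasing when
#' down-sampling from the native 7.7 kHz rate), reshaped onto the electrode
#' grid.
#'
#' @param rec a [voltage_recording()].
#' @param window `c(start_s, end_s)` within the recording, or `NULL` for the
#'   whole recording.
#' @param frame_interval frame spacing in s (default 1 ms); must satisfy
#'   `sampling_rate * frame_interval >= 1`.
#' @return A [snapshot_stack()] with `floor(window length / frame_interval)`
#'   frames.
#' @examples
#' lay <- electrode_layout(8, 8)
#' rec <- generate_baseline(duration = 0.5, frame_rate = 1000, layout = lay)
#' extract_snapshots(rec, frame_interval = 0.01)   # 50 frames
#' @export
extract_snapshots <- function(rec, window = NULL, frame_interval = 0.001) {
  stopifnot(inherits(rec, "voltage_recording"), frame_interval > 0)
  fs <- rec$sampling_rate
  if (fs * frame_interval < 1 - 1e-9)
    stop("frame_interval shorter than one sample")
  dur <- recording_duration(rec)
  if (is.null(window)) window <- c(0, dur)
  if (window[1] < -1e-9 || window[2] > dur + 1e-9 || window[2] <= window[1])
    stop("window must be non-empty and lie within the recording")
  i0 <- round(window[1] * fs)                    # 0-based sample offset
  len <- window[2] - window[1]
  nf <- floor(len / frame_interval + 1e-9)
  if (nf < 1) stop("window shorter than one frame")
  spp <- fs * frame_interval                     # samples per frame (may be fractional)
  lay <- rec$layout
  frames <- array(0, dim = c(lay$n_rows, lay$n_cols, nf))
  for (f in seq_len(nf)) {
    a <- i0 + floor((f - 1) * spp + 1e-9) + 1
    b <- i0 + floor(f * spp + 1e-9)
    seg <- rec$voltage[, a:b, drop = FALSE]
    frames[, , f] <- matrix(rowMeans(seg), lay$n_rows, lay$n_cols)
  }
  snapshot_stack(frames, frame_interval, window)
}

#' Select evenly spaced frames from a stack
#'
#' Returns `k` frames at indices `round(seq(first, last, length.out = k))`;
#' the first and last frames are always included.  This is the 6-snapshot
#' sampling used for complexity estimation and for assembling the
#' adversarial-network training set (evenly spaced time points between wave
#' initiation and termination).
#'
#' @param stack a [snapshot_stack()] with at least `k` frames.
#' @param k number of frames (>= 2).
#' @return A [snapshot_stack()] of `k` frames.
#' @export
select_evenly_spaced <- function(stack, k = 6L) {
  stopifnot(inherits(stack, "snapshot_stack"))
  if (k < 2) stop("k must be >= 2")
  nf <- n_frames(stack)
  if (nf < k) stop("stack has fewer than k frames")
  idx <- round(seq(1, nf, length.out = k))
  subset_frames(stack, idx)
}
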