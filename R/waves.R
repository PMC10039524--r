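#' Activity-weighted centre of mass of a snapshot
#'
#' The centre row and column are the activity-weighted means
#' `r = sum(i * a_ij) / sum(a_ij)`, `c = sum(j * a_ij) / sum(a_ij)` over the
#' electrode grid (1-based indices).  Band-filtered voltage is oscillatory,
#' so the default weights are `|a_ij|`, which keeps the denominator positive
#' at every frame; `"signed"` applies the formula literally and `"squared"`
#' uses `a_ij^2`.
#'
#' @param frame rows x cols activity matrix.
#' @param weight_mode `"absolute"` (default), `"signed"`, or `"squared"`.
#' @return list of class `center_of_mass` with fractional `r` and `c`.
#' @examples
#' f <- matrix(0, 3, 3); f[2, 2] <- 2; f[3, 3] <- 2
#' center_of_mass(f)   # (2.5, 2.5)
#' @export
center_of_mass <- function(frame,
                           weight_mode = c("absolute", "signed", "squared")) {
  weight_mode <- match.arg(weight_mode)
  w <- switch(weight_mode, absolute = abs(frame), signed = frame,
              squared = frame^2)
  s <- sum(w)
  if (!is.finite(s) || s == 0) stop("undefined centre: weights sum to zero")
  i <- row(frame); j <- col(frame)
  structure(list(r = sum(i * w) / s, c = sum(j * w) / s),
            class = "center_of_mass")
}

#' Mean centre of mass of a wave
#'
#' Per-frame centres of mass averaged over the wave (unweighted), plus the
#' per-frame scatter (RMS distance from the mean centre).  Frames with an
#' undefined centre are excluded with a warning.
#'
#' @param stack a [snapshot_stack()].
#' @param weight_mode passed to [center_of_mass()].
#' @return list with `r`, `c`, `scatter` (grid units), and `per_frame`
#'   (data.frame of per-frame centres).
#' @export
wave_center <- function(stack, weight_mode = "absolute") {
  stopifnot(inherits(stack, "snapshot_stack"))
  nf <- n_frames(stack)
  rs <- cs <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    cm <- tryCatch(center_of_mass(get_frame(stack, f), weight_mode),
                   error = function(e) NULL)
    if (!is.null(cm)) { rs[f] <- cm$r; cs[f] <- cm$c }
  }
  ok <- is.finite(rs)
  if (!any(ok)) stop("no frame has a defined centre")
  if (any(!ok)) warning(sum(!ok), " frame(s) with undefined centre excluded")
  r <- mean(rs[ok]); c <- mean(cs[ok])
  scatter <- sqrt(mean((rs[ok] - r)^2 + (cs[ok] - c)^2))
  list(r = r, c = c, scatter = scatter,
       per_frame = data.frame(frame = which(ok), r = rs[ok], c = cs[ok]))
}

#' Refine a rotation-core estimate via the amplitude dip
#'
#' The activity-weighted centre of mass is biased by background mass and
#' envelope lumpiness; the rotation core itself is marked by the local
#' minimum of voltage amplitude.  Starting from `start`, this finds the
#' minimum of the (Gaussian-smoothed) time-averaged `|v|` surface within
#' `search_radius` grid units and returns its centroid-interpolated
#' position.
#'
#' @param stack a [snapshot_stack()].
#' @param start `(row, col)` initial centre (e.g. the centre of mass).
#' @param search_radius search window in grid units.
#' @param smooth_sigma smoothing of the amplitude surface (grid units).
#' @return `(row, col)` refined core position.
#' @export
refine_core <- function(stack, start, search_radius = 5, smooth_sigma = 1.5) {
  stopifnot(inherits(stack, "snapshot_stack"))
  d <- dim(stack$frames)
  amp <- matrix(rowMeans(abs(as_channel_matrix(stack))), d[1], d[2])
  amp <- smooth_field_2d(amp, smooth_sigma)
  rs <- pmax(2, round(start[1]) - search_radius):
    pmin(d[1] - 1, round(start[1]) + search_radius)
  cs <- pmax(2, round(start[2]) - search_radius):
    pmin(d[2] - 1, round(start[2]) + search_radius)
  sub <- amp[rs, cs, drop = FALSE]
  ix <- which(sub == min(sub), arr.ind = TRUE)[1, ]
  r0 <- rs[ix[1]]; c0 <- cs[ix[2]]
  ## centroid of inverted amplitude over the 3x3 neighbourhood (sub-pixel)
  nb_r <- (r0 - 1):(r0 + 1); nb_c <- (c0 - 1):(c0 + 1)
  w <- max(amp[nb_r, nb_c]) - amp[nb_r, nb_c] + 1e-12
  c(sum(outer(nb_r, rep(1, 3)) * w) / sum(w),
    sum(outer(rep(1, 3), nb_c) * w) / sum(w))
}

## winding numbers across (a subsample of) frames at a fixed centre
frame_windings <- function(phases, center, radius, max_frames = 60L) {
  nf <- n_frames(phases)
  idx <- unique(round(seq(1, nf, length.out = min(nf, max_frames))))
  vapply(idx, function(f)
    tryCatch(winding_number(get_frame(phases, f), center, radius),
             error = function(e) NA_integer_), integer(1))
}

## largest circle radius about `center` that stays inside the grid
max_radius <- function(dims, center) {
  floor(min(center[1] - 1, dims[1] - center[1],
            center[2] - 1, dims[2] - center[2]))
}

#' Rotation direction of a spiral wave
#'
#' Sign of the median winding number across frames, mapped to the package's
#' coordinate convention: positive winding = counter-clockwise (CCW),
#' negative = clockwise (CW).  A zero median yields `"none"`.
#'
#' @param phases a `phase_stack` from [instantaneous_phase()].
#' @param center `(row, col)` rotation centre.
#' @param radius circle radius in grid units; default a quarter of the
#'   smaller grid dimension, shrunk to fit around `center`.
#' @return `"CCW"`, `"CW"`, or `"none"`.
#' @export
rotation_direction <- function(phases, center, radius = NULL) {
  dims <- dim(phases$frames)
  if (is.null(radius))
    radius <- min(floor(min(dims[1:2]) / 4), max_radius(dims[1:2], center))
  w <- frame_windings(phases, center, radius)
  med <- stats::median(w, na.rm = TRUE)
  if (!is.finite(med) || med == 0) return("none")
  if (med > 0) "CCW" else "CW"
}

#' Count rotation cycles of a spiral wave
#'
#' Total unwrapped phase advance at a probe electrode about a quarter array
#' width from the centre, divided by `2 pi` and floored.  The advance is
#' measured by a linear fit to the unwrapped phase over the central 80% of
#' the window (robust to analytic-signal edge effects) and extrapolated to
#' the full window; a small tolerance (0.05 cycles) guards the floor against
#' numerical jitter at integer boundaries.
#'
#' @param phases a `phase_stack`.
#' @param center `(row, col)` rotation centre.
#' @param probe_radius radius of the probe electrode in grid units
#'   (default a quarter of the smaller grid dimension, shrunk to fit).
#' @return integer cycle count (>= 0).
#' @export
count_cycles <- function(phases, center, probe_radius = NULL) {
  dims <- dim(phases$frames)
  if (is.null(probe_radius))
    probe_radius <- min(floor(min(dims[1:2]) / 4),
                        max_radius(dims[1:2], center))
  ## probe along +column if it fits, otherwise the opposite side
  pc <- round(center[2]) + probe_radius
  pr <- round(center[1])
  if (pc > dims[2]) pc <- round(center[2]) - probe_radius
  pr <- min(max(pr, 1), dims[1])
  ph <- phases$frames[pr, pc, ]
  if (stats::sd(ph) == 0) return(0L)
  unph <- cumsum(c(ph[1], wrap_phase(diff(ph))))
  nf <- length(unph)
  sel <- seq(max(1, round(0.1 * nf)), min(nf, round(0.9 * nf)))
  slope <- stats::coef(stats::lm(unph[sel] ~ sel))[2]
  advance <- abs(slope) * (nf - 1)
  max(0L, as.integer(floor(advance / (2 * pi) + 0.05)))
}

#' Thresholds for wave classification
#'
#' Defaults for the four spiral criteria and the planar test.  The values
#' (phase-spread resultant < 0.4, core-dip ratio 0.8 on a disk of radius 3
#' vs. an annulus of 6-12 grid units, vector-alignment resultant > 0.8,
#' envelope threshold 3 MAD over 0.5 s) replace the visual inspection used
#' on real slices and are all configurable.
#'
#' @param phase_spread_max max circular resultant of phases for "broad".
#' @param dip_ratio core/surround mean-activity ratio threshold.
#' @param dip_disk,dip_annulus disk radius and annulus radii (grid units).
#' @param planar_alignment_min min vector-angle resultant for planar.
#' @param corr_p_max significance level for the correlation-distance slope.
#' @param envelope_mads detection threshold in MADs above the median.
#' @param min_duration_s,merge_gap_s segmentation parameters in s.
#' @return named list of thresholds.
#' @export
wave_thresholds <- function(phase_spread_max = 0.4, dip_ratio = 0.8,
                            dip_disk = 3, dip_annulus = c(6, 12),
                            planar_alignment_min = 0.8, corr_p_max = 0.05,
                            envelope_mads = 3, min_duration_s = 0.5,
                            merge_gap_s = 0.25) {
  as.list(environment())
}

#' Classify a snapshot stack as spiral, planar, or other
#'
#' Computes the four spiral-verification criteria: (i) broad instantaneous
#' phase distribution around the centre of mass (mean per-frame circular
#' resultant, over electrodes within the outer annulus radius, below
#' threshold);
#' (ii) rotating vector fields, automated as an absolute median winding
#' number >= 1 about the centre of mass; (iii) reduced activity near the
#' centre of mass (disk/annulus mean ratio); (iv) spatially-dependent
#' correlations (negative, significant correlation-vs-distance slope).  A
#' stack is a spiral iff all four hold; it is planar if the vector-field
#' angles are concentrated (resultant above threshold) with zero winding;
#' otherwise "other".  Deterministic: no randomness is involved.
#'
#' @param stack a [snapshot_stack()] with >= 50 frames.
#' @param layout an [electrode_layout()] matching the stack (used for
#'   distances); default derives a layout from the stack dimensions.
#' @param thresholds a [wave_thresholds()] list.
#' @return A `wave_event` list: `kind`, `center`, `direction`, `cycles`,
#'   `criteria` (four booleans), `stats` (the numbers behind them), and the
#'   `window` of the stack.
#' @export
classify_wave <- function(stack, layout = NULL,
                          thresholds = wave_thresholds()) {
  stopifnot(inherits(stack, "snapshot_stack"))
  if (n_frames(stack) < 50) stop("need >= 50 frames to classify")
  dims <- dim(stack$frames)
  if (is.null(layout)) layout <- electrode_layout(dims[1], dims[2])
  th <- thresholds
  phases <- instantaneous_phase(stack)
  ## squared weights: robust to diffuse background mass riding under a wave
  ctr <- wave_center(stack, weight_mode = "squared")
  ## criteria are evaluated about the rotation core: the amplitude-dip
  ## refinement of the centre of mass (the CoM itself is also reported)
  center <- refine_core(stack, c(ctr$r, ctr$c))

  ## (i) broad phase distribution around the centre of mass
  nf <- n_frames(stack)
  fidx <- unique(round(seq(1, nf, length.out = min(nf, 40))))
  dmat <- sqrt((layout$row - center[1])^2 + (layout$col - center[2])^2)
  near <- dmat <= th$dip_annulus[2]
  rbar <- mean(vapply(fidx, function(f)
    resultant_length(as.vector(get_frame(phases, f))[near]), numeric(1)))
  broad <- is.finite(rbar) && rbar < th$phase_spread_max

  ## (ii) rotating vector fields via the winding number
  radius <- min(floor(min(dims[1:2]) / 4), max_radius(dims[1:2], center))
  wmed <- if (radius >= 2)
    stats::median(frame_windings(phases, center, radius), na.rm = TRUE)
  else NA_real_
  rotating <- is.finite(wmed) && abs(wmed) >= 1

  ## (iii) voltage dip at the centre of mass
  absmean <- rowMeans(abs(as_channel_matrix(stack)))
  core <- dmat <= th$dip_disk
  ann <- dmat >= th$dip_annulus[1] & dmat <= th$dip_annulus[2]
  dip_stat <- if (any(core) && any(ann))
    mean(absmean[core]) / mean(absmean[ann]) else NA_real_
  dip <- is.finite(dip_stat) && dip_stat < th$dip_ratio

  ## (iv) spatially-dependent correlations
  corr <- pairwise_correlations(stack)
  cvd <- correlation_vs_distance(corr, layout)
  corr_dep <- is.finite(cvd$slope) && cvd$slope < 0 &&
    is.finite(cvd$p_value) && cvd$p_value < th$corr_p_max

  ## planar test: aligned vector fields, no singularity; sample the central
  ## 70% of the window to stay clear of analytic-signal edge effects
  lag <- max(0.010, phases$frame_interval)
  dur <- (nf - 1) * phases$frame_interval
  tpts <- seq(0.15 * dur, 0.85 * dur - lag,
              length.out = min(8, max(2, floor(0.7 * dur / lag))))
  angles <- unlist(lapply(tpts, function(t0)
    vector_field_angles(vector_field(phases, t0, lag))))
  alignment <- resultant_length(angles)

  criteria <- c(broad_phases = broad, rotating = rotating, core_dip = dip,
                distance_corr = corr_dep)
  kind <- if (all(criteria)) "spiral"
  else if (is.finite(alignment) && alignment > th$planar_alignment_min &&
           is.finite(wmed) && wmed == 0) "planar"
  else "other"

  direction <- "none"; cycles <- NA_integer_
  if (kind == "spiral") {
    direction <- rotation_direction(phases, center, radius)
    if (direction == "none") kind <- "other"
    else cycles <- count_cycles(phases, center)
  }

  structure(list(
    kind = kind, window = stack$window,
    center = ctr, core = center, direction = direction, cycles = cycles,
    criteria = criteria,
    stats = list(phase_resultant = rbar, median_winding = wmed,
                 dip_ratio = dip_stat, corr_slope = cvd$slope,
                 corr_p = cvd$p_value, vector_alignment = alignment,
                 duration_s = nf * stack$frame_interval,
                 n_frames = nf)
  ), class = "wave_event")
}

#' @export
print.wave_event <- function(x, ...) {
  cat(sprintf("<wave_event> %s  centre (%.1f, %.1f)  direction %s  cycles %s\n",
              x$kind, x$center$r, x$center$c, x$direction,
              ifelse(is.na(x$cycles), "-", x$cycles)))
  cat("  criteria:", paste(names(x$criteria), unname(x$criteria),
                           sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Detect and classify waves in a recording
#'
#' Automated segmentation standing in for manual visual inspection: the
#' array-mean instantaneous-amplitude envelope of the (delta-filtered,
#' cleaned) recording is thresholded at `median + 3 MAD`; excursions lasting
#' at least `min_duration_s` (gaps below `merge_gap_s` merged) become
#' candidate windows, each classified with [classify_wave()].  Event
#' duration is the length of the detected window (consecutive frames where
#' the wave is identified).
#'
#' @param rec a cleaned, delta-band-filtered [voltage_recording()].
#' @param frame_interval snapshot interval in s.
#' @param thresholds a [wave_thresholds()] list.
#' @return list with `events` (list of `wave_event`), `table` (one row per
#'   event), `rate_per_min` (spiral rate), and `duration_mean_s` /
#'   `duration_sd_s` of spiral events.
#' @export
detect_waves <- function(rec, frame_interval = 0.001,
                         thresholds = wave_thresholds()) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (ncol(rec$voltage) == 0)
    return(list(events = list(), table = empty_wave_table(),
                rate_per_min = 0, duration_mean_s = NA_real_,
                duration_sd_s = NA_real_))
  stack <- extract_snapshots(rec, frame_interval = frame_interval)
  X <- t(as_channel_matrix(stack))              # time x channels
  env <- rowMeans(Mod(analytic_signal(sweep(X, 2, colMeans(X)))))
  ## baseline statistics from the lower half of the envelope distribution,
  ## so that a high wave duty cycle cannot inflate the threshold
  base <- env[env <= stats::median(env)]
  thr <- stats::median(base) + thresholds$envelope_mads * stats::mad(base)
  above <- env > thr
  segs <- runs_to_segments(above, frame_interval,
                           thresholds$min_duration_s, thresholds$merge_gap_s)
  events <- list()
  for (k in seq_len(nrow(segs))) {
    idx <- segs$i0[k]:segs$i1[k]
    if (length(idx) < 50) next
    sub <- subset_frames(stack, idx)
    sub$window <- c((segs$i0[k] - 1) * frame_interval,
                    segs$i1[k] * frame_interval)
    ev <- tryCatch(classify_wave(sub, rec$layout, thresholds),
                   error = function(e) NULL)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  tab <- if (length(events)) do.call(rbind, lapply(seq_along(events),
    function(i) {
      e <- events[[i]]
      data.frame(event_id = i, kind = e$kind,
                 start_s = e$window[1], end_s = e$window[2],
                 center_row = e$center$r, center_col = e$center$c,
                 direction = e$direction, cycles = e$cycles,
                 duration_s = e$stats$duration_s,
                 broad_phases = e$criteria[["broad_phases"]],
                 rotating = e$criteria[["rotating"]],
                 core_dip = e$criteria[["core_dip"]],
                 distance_corr = e$criteria[["distance_corr"]])
    })) else empty_wave_table()
  spir <- tab[tab$kind == "spiral", , drop = FALSE]
  dur_total_min <- recording_duration(rec) / 60
  list(events = events, table = tab,
       rate_per_min = nrow(spir) / dur_total_min,
       duration_mean_s = if (nrow(spir)) mean(spir$duration_s) else NA_real_,
       duration_sd_s = if (nrow(spir) > 1) stats::sd(spir$duration_s)
       else NA_real_)
}

empty_wave_table <- function() {
  data.frame(event_id = integer(), kind = character(), start_s = numeric(),
             end_s = numeric(), center_row = numeric(), center_col = numeric(),
             direction = character(), cycles = integer(),
             duration_s = numeric(), broad_phases = logical(),
             rotating = logical(), core_dip = logical(),
             distance_corr = logical())
}

## logical run-length segmentation with minimum duration and gap merging
runs_to_segments <- function(above, dt, min_dur, merge_gap) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  if (!nrow(seg)) return(seg)
  ## merge segments separated by short gaps
  merged <- seg[1, ]
  if (nrow(seg) > 1) {
    for (k in 2:nrow(seg)) {
      gap <- (seg$i0[k] - merged$i1[nrow(merged)] - 1) * dt
      if (gap < merge_gap) merged$i1[nrow(merged)] <- seg$i1[k]
      else merged <- rbind(merged, seg[k, ])
    }
  }
  merged[(merged$i1 - merged$i0 + 1) * dt >= min_dur, , drop = FALSE]
}
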