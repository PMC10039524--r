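#' Parameters of a synthetic spiral wave
#'
#' The simulator is phenomenological: a rotating Archimedean-phase pattern
#' `v(rho, theta, t) = A(rho) * E(rho, theta) * cos(2 pi f t - m theta + k rho)
#' + noise`, where `A(rho) = amplitude * rho / (rho + dip_radius)` enforces
#' the voltage dip at the rotation core, and `E` is a seeded smooth positive
#' random field ("domains" of stronger and weaker participation, mean 1).
#' `theta` is measured counter-clockwise in the flipped-y frame (see
#' [electrode_layout()]); positive `m` therefore rotates counter-clockwise.
#'
#' Defaults describe a typical disinhibited-cortex delta-band wave: 100 uV
#' amplitude, 1-4 Hz temporal frequency, a core dip of about three electrode
#' pitches, a radial wavelength of about 1.2 mm, domain structure on the
#' ~200 um scale, and an additive noise floor of 10% of the wave amplitude
#' (epileptiform background activity is far from clean).  The window slightly
#' exceeds the programmed number of rotations (`duration = (cycles + 0.1) /
#' frequency` unless given) the way manually segmented waves include margins.
#'
#' @param center `(row, col)` rotation centre in 1-based grid coordinates.
#' @param frequency temporal frequency in Hz, in `[1, 4]` (delta band).
#' @param m signed arm count; sign is the rotation direction (positive =
#'   counter-clockwise).
#' @param cycles programmed number of full rotations (positive integer,
#'   must satisfy `duration * frequency >= cycles`).
#' @param dip_radius core amplitude-dip radius in um.
#' @param wavenumber radial wavenumber in rad/um.
#' @param amplitude peak voltage amplitude in uV (> 0).
#' @param envelope_smoothness correlation length of the domain envelope, um.
#' @param envelope_depth log-SD of the domain envelope (0 = flat envelope).
#' @param domain_radius radius (um) of the active domain around the
#'   rotation core (`Inf` disables); the taper is a flat-top super-Gaussian
#'   `exp(-(rho/R)^4 / 2)`, i.e. full wave amplitude out to roughly `R` and
#'   a rapid fall-off beyond.  Activity in real slices is delimited to a
#'   domain around the centre of mass; without this cut-off the
#'   activity-weighted centre would sit at the grid centre instead of the
#'   rotation core.
#' @param noise_sd additive white-noise SD in uV.
#' @param duration window length in s, or `NULL` for `(cycles + 0.1) /
#'   frequency`.
#' @param frame_rate frames per second (>= 2 * frequency).
#' @param seed integer seed.
#' @return A `spiral_params` list, validated.
#' @export
spiral_params <- function(center = c(32, 32), frequency = 2, m = 1L,
                          cycles = 2L, dip_radius = 200, wavenumber = 2 * pi / 1200,
                          amplitude = 100, envelope_smoothness = 200,
                          envelope_depth = 0.2, domain_radius = 550,
                          noise_sd = 10, duration = NULL, frame_rate = 1000,
                          seed = 1L) {
  if (is.null(duration)) duration <- (cycles + 0.1) / frequency
  p <- list(center = center, frequency = frequency, m = as.integer(m),
            cycles = as.integer(cycles), dip_radius = dip_radius,
            wavenumber = wavenumber, amplitude = amplitude,
            envelope_smoothness = envelope_smoothness,
            envelope_depth = envelope_depth, domain_radius = domain_radius,
            noise_sd = noise_sd,
            duration = duration, frame_rate = frame_rate,
            seed = as.integer(seed))
  validate_spiral_params(p)
  structure(p, class = "spiral_params")
}

validate_spiral_params <- function(p) {
  stopifnot(length(p$center) == 2, p$amplitude > 0, p$cycles >= 1,
            p$m != 0, p$noise_sd >= 0, p$dip_radius >= 0, p$duration > 0)
  if (p$duration * p$frequency < p$cycles)
    stop("duration * frequency must be >= cycles")
  if (p$frame_rate < 2 * p$frequency)
    stop("frame rate below Nyquist for the programmed temporal frequency")
  invisible(p)
}

## polar coordinates of every electrode about a (row, col) centre;
## theta counter-clockwise in the flipped-y frame, rho in um
polar_about <- function(layout, center) {
  dr <- layout$row - center[1]
  dc <- layout$col - center[2]
  list(rho = sqrt(dr^2 + dc^2) * layout$pitch,
       theta = atan2(-dr, dc))
}

## seeded smooth positive envelope, mean ~1 (log-normal of a smoothed field)
domain_envelope <- function(layout, smoothness_um, depth, seed) {
  if (depth <= 0) return(rep(1, layout$n_channels))
  sigma_px <- smoothness_um / layout$pitch
  g <- with_seed(seed,
                 gaussian_random_field(layout$n_rows, layout$n_cols, sigma_px))
  g <- g / stats::sd(g) * depth
  e <- exp(g)
  as.vector(e) / mean(e)
}

#' Generate a synthetic spiral-wave recording
#'
#' @param params a [spiral_params()] object.
#' @param layout an [electrode_layout()]; the centre must lie inside it.
#' @return A [voltage_recording()] of `duration * frame_rate` frames at
#'   `frame_rate` Hz with provenance `"synthetic-spiral"`.
#' @examples
#' lay <- electrode_layout(16, 16, 42)
#' rec <- generate_spiral_wave(spiral_params(center = c(8, 8), noise_sd = 0,
#'                                           frame_rate = 250), lay)
#' @export
generate_spiral_wave <- function(params, layout = electrode_layout()) {
  validate_spiral_params(params)
  if (params$center[1] < 1 || params$center[1] > layout$n_rows ||
      params$center[2] < 1 || params$center[2] > layout$n_cols)
    stop("spiral centre lies outside the electrode grid")
  pol <- polar_about(layout, params$center)
  amp <- params$amplitude * pol$rho / (pol$rho + params$dip_radius)
  if (is.finite(params$domain_radius))
    amp <- amp * exp(-0.5 * (pol$rho / params$domain_radius)^4)
  env <- domain_envelope(layout, params$envelope_smoothness,
                         params$envelope_depth, params$seed)
  n_t <- round(params$duration * params$frame_rate)
  t <- (seq_len(n_t) - 1) / params$frame_rate
  ## spatial phase offset: -m*theta + k*rho
  phi0 <- -params$m * pol$theta + params$wavenumber * pol$rho
  v <- (amp * env) * cos(outer(phi0, 2 * pi * params$frequency * t, `+`))
  if (params$noise_sd > 0) {
    v <- v + with_seed(params$seed + 1L,
                       matrix(stats::rnorm(length(v), 0, params$noise_sd),
                              nrow(v), ncol(v)))
  }
  voltage_recording(v, params$frame_rate, layout, provenance = "synthetic-spiral")
}

#' Generate a synthetic planar-wave recording
#'
#' `v = amplitude * cos(2 pi f t - k (x cos(alpha) + y sin(alpha))) + noise`
#' with `(x, y)` the electrode positions in the flipped-y frame, so the wave
#' propagates along `direction_angle` (counter-clockwise from the +x axis).
#'
#' @param direction_angle propagation direction in radians.
#' @param frequency temporal frequency in Hz.
#' @param wavenumber spatial wavenumber in rad/um.
#' @param amplitude amplitude in uV.
#' @param noise_sd additive white-noise SD in uV.
#' @param duration window length in s.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @param layout an [electrode_layout()].
#' @return A [voltage_recording()] with provenance `"synthetic-planar"`.
#' @export
generate_planar_wave <- function(direction_angle = 0, frequency = 2,
                                 wavenumber = 2 * pi / 1200, amplitude = 100,
                                 noise_sd = 10, duration = 1.05,
                                 frame_rate = 1000, seed = 1L,
                                 layout = electrode_layout()) {
  stopifnot(amplitude > 0, noise_sd >= 0, duration > 0)
  if (frame_rate < 2 * frequency)
    stop("frame rate below Nyquist for the programmed temporal frequency")
  x <- layout$x_um
  y <- -layout$y_um                      # flipped-y frame
  phi0 <- -wavenumber * (x * cos(direction_angle) + y * sin(direction_angle))
  n_t <- round(duration * frame_rate)
  t <- (seq_len(n_t) - 1) / frame_rate
  v <- amplitude * cos(outer(phi0, 2 * pi * frequency * t, `+`))
  if (noise_sd > 0) {
    v <- v + with_seed(seed + 1L,
                       matrix(stats::rnorm(length(v), 0, noise_sd),
                              nrow(v), ncol(v)))
  }
  voltage_recording(v, frame_rate, layout, provenance = "synthetic-planar")
}

#' Generate baseline (no-wave) activity
#'
#' Spatiotemporally correlated Gaussian noise: white fields are smoothed with
#' a Gaussian kernel of width `spatial_corr_length` and combined over time by
#' an AR(1) process with time constant `temporal_corr`, then scaled so each
#' electrode has SD `noise_sd`.  No phase singularity is programmed.
#'
#' The defaults (10 uV, 150 um, 0.15 s) emulate quiet pre-disinhibition
#' recordings dominated by widespread slow co-fluctuation.
#'
#' @param noise_sd per-electrode SD in uV.
#' @param spatial_corr_length Gaussian smoothing length in um (0 = white).
#' @param temporal_corr AR(1) time constant in s (0 = temporally white).
#' @param duration length in s.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @param layout an [electrode_layout()].
#' @return A [voltage_recording()] with provenance `"synthetic-baseline"`.
#' @export
generate_baseline <- function(noise_sd = 10, spatial_corr_length = 150,
                              temporal_corr = 0.15, duration = 2,
                              frame_rate = 1000, seed = 1L,
                              layout = electrode_layout()) {
  stopifnot(noise_sd >= 0, spatial_corr_length >= 0, temporal_corr >= 0,
            duration > 0, frame_rate > 0)
  n_t <- round(duration * frame_rate)
  sigma_px <- spatial_corr_length / layout$pitch
  phi <- if (temporal_corr > 0) exp(-1 / (frame_rate * temporal_corr)) else 0
  v <- matrix(0, layout$n_channels, n_t)
  with_seed(seed, {
    innov_scale <- NULL
    state <- NULL
    for (ti in seq_len(n_t)) {
      eps <- as.vector(gaussian_random_field(layout$n_rows, layout$n_cols,
                                             sigma_px))
      if (is.null(innov_scale)) {
        ## smoothing shrinks the variance; fix the innovation scale once from
        ## the kernel so the process stays strictly seeded and stationary
        innov_scale <- sqrt(mean(eps^2) + 1e-12)
      }
      eps <- eps / innov_scale
      state <- if (is.null(state)) eps else phi * state + sqrt(1 - phi^2) * eps
      v[, ti] <- state
    }
  })
  v <- v * noise_sd
  voltage_recording(v, frame_rate, layout, provenance = "synthetic-baseline")
}

#' Add seeded Gaussian noise to a snapshot stack
#'
#' Element-wise addition of i.i.d. Gaussian values, used to probe how noise
#' statistics move the participation ratio of wave snapshots.
#'
#' @param stack a [snapshot_stack()].
#' @param mean noise mean in uV.
#' @param sd noise SD in uV (>= 0).
#' @param seed integer seed.
#' @return A [snapshot_stack()] of the same dimensions.
#' @export
add_gaussian_noise <- function(stack, mean = 0, sd = 0, seed = 1L) {
  stopifnot(inherits(stack, "snapshot_stack"), sd >= 0)
  fr <- stack$frames
  if (sd > 0 || mean != 0) {
    noise <- if (sd > 0)
      with_seed(seed, array(stats::rnorm(length(fr), mean, sd), dim = dim(fr)))
    else array(mean, dim = dim(fr))
    fr <- fr + noise
  }
  snapshot_stack(fr, stack$frame_interval, stack$window)
}

#' Specification of a synthetic dataset
#'
#' @param n_spiral_cw,n_spiral_ccw numbers of clockwise / counter-clockwise
#'   spiral events.
#' @param n_planar number of planar-wave events.
#' @param duration_mean,duration_sd event duration distribution in s
#'   (normal truncated below at `duration_min`).
#' @param duration_min lower truncation bound in s.
#' @param frequency_range range of temporal frequencies in Hz.
#' @param gap_s baseline gap between events in s (about 7 events/min at the
#'   default 5 s gap and 2.5 s durations).
#' @param amplitude,noise_sd wave amplitude and additive noise SD in uV.
#' @param baseline_sd,baseline_corr_length,baseline_temporal_corr background
#'   activity parameters, as in [generate_baseline()].
#' @param frame_rate frames per second.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_spiral_cw = 5L, n_spiral_ccw = 5L, n_planar = 0L,
                         duration_mean = 2.52, duration_sd = 1.00,
                         duration_min = 0.6, frequency_range = c(1, 2),
                         gap_s = 5, amplitude = 100, noise_sd = 10,
                         baseline_sd = 10, baseline_corr_length = 150,
                         baseline_temporal_corr = 0.15, frame_rate = 1000) {
  structure(as.list(environment()), class = "dataset_spec")
}

#' Generate a full synthetic recording with ground-truth annotations
#'
#' Concatenates seeded spiral and planar events separated by baseline gaps;
#' the correlated baseline background runs under the whole recording (waves
#' ride on background activity, as in real slices).  Event durations are
#' drawn from a truncated normal, frequencies uniformly from
#' `frequency_range`; the programmed cycle count of a spiral is
#' `floor(frequency * duration)`.  Event order interleaves the requested
#' kinds deterministically under the seed.
#'
#' @param spec a [dataset_spec()].
#' @param seed integer seed.
#' @param layout an [electrode_layout()].
#' @return A list with `recording` (a [voltage_recording()]) and
#'   `ground_truth` (a data.frame: event_id, kind, start_s, end_s,
#'   center_row, center_col, direction, cycles).
#' @export
generate_dataset <- function(spec = dataset_spec(), seed = 1L,
                             layout = electrode_layout()) {
  stopifnot(inherits(spec, "dataset_spec"))
  n_ev <- spec$n_spiral_cw + spec$n_spiral_ccw + spec$n_planar
  kinds <- c(rep("spiral_cw", spec$n_spiral_cw),
             rep("spiral_ccw", spec$n_spiral_ccw),
             rep("planar", spec$n_planar))
  fr <- spec$frame_rate
  gt <- list()
  with_seed(derive_seed(seed, "dataset"), {
    kinds <- if (n_ev) sample(kinds) else character()
    durations <- if (n_ev)
      rtruncnorm_lower(n_ev, spec$duration_mean, spec$duration_sd,
                       spec$duration_min) else numeric()
    freqs <- if (n_ev)
      stats::runif(n_ev, spec$frequency_range[1], spec$frequency_range[2])
      else numeric()
    centers_r <- if (n_ev)
      stats::runif(n_ev, 0.3 * layout$n_rows, 0.7 * layout$n_rows) else numeric()
    centers_c <- if (n_ev)
      stats::runif(n_ev, 0.3 * layout$n_cols, 0.7 * layout$n_cols) else numeric()
    angles <- if (n_ev) stats::runif(n_ev, 0, 2 * pi) else numeric()
  })

  total_dur <- spec$gap_s * (n_ev + 1) + sum(if (n_ev) durations else 0)
  n_t <- round(total_dur * fr)
  base <- generate_baseline(spec$baseline_sd, spec$baseline_corr_length,
                            spec$baseline_temporal_corr, total_dur, fr,
                            seed = derive_seed(seed, "background"), layout)
  v <- base$voltage

  t_cursor <- spec$gap_s
  for (i in seq_len(n_ev)) {
    dur <- durations[i]
    f <- freqs[i]
    start <- t_cursor
    end <- start + dur
    i0 <- round(start * fr) + 1L
    kind <- kinds[i]
    ev_seed <- derive_seed(seed, paste0("event", i))
    if (kind == "planar") {
      ev <- generate_planar_wave(angles[i], f, amplitude = spec$amplitude,
                                 noise_sd = spec$noise_sd, duration = dur,
                                 frame_rate = fr, seed = ev_seed,
                                 layout = layout)
      gt[[i]] <- data.frame(event_id = i, kind = "planar", start_s = start,
                            end_s = end, center_row = NA_real_,
                            center_col = NA_real_, direction = "none",
                            cycles = NA_integer_)
    } else {
      m <- if (kind == "spiral_ccw") 1L else -1L
      ## short windows still hold at least one full rotation
      f <- max(f, 1.05 / dur)
      cyc <- max(1L, floor(f * dur))
      p <- spiral_params(center = c(centers_r[i], centers_c[i]), frequency = f,
                         m = m, cycles = cyc, amplitude = spec$amplitude,
                         noise_sd = spec$noise_sd, duration = dur,
                         frame_rate = fr, seed = ev_seed)
      ev <- generate_spiral_wave(p, layout)
      gt[[i]] <- data.frame(event_id = i, kind = "spiral", start_s = start,
                            end_s = end, center_row = centers_r[i],
                            center_col = centers_c[i],
                            direction = if (m > 0) "CCW" else "CW",
                            cycles = cyc)
    }
    idx <- i0:(i0 + ncol(ev$voltage) - 1L)
    idx <- idx[idx <= n_t]
    v[, idx] <- v[, idx] + ev$voltage[, seq_along(idx)]
    t_cursor <- end + spec$gap_s
  }

  ground_truth <- if (length(gt)) do.call(rbind, gt)
  else data.frame(event_id = integer(), kind = character(),
                  start_s = numeric(), end_s = numeric(),
                  center_row = numeric(), center_col = numeric(),
                  direction = character(), cycles = integer())
  list(recording = voltage_recording(v, fr, layout,
                                     provenance = "synthetic-dataset"),
       ground_truth = ground_truth)
}
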