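#' Instantaneous phase of a snapshot stack
#'
#' Computes, for every electrode, the phase angle of the analytic signal
#' (Hilbert transform) of its frame-by-frame time series, wrapped to
#' `[-pi, pi)`.  Electrodes with zero temporal variance have no defined
#' phase; their phase is set to 0 and they are flagged.
#'
#' @param stack a [snapshot_stack()] with at least 8 frames.
#' @return A `phase_stack`: like a snapshot stack but `frames` holds phases
#'   in radians; field `degenerate` is a logical matrix marking zero-variance
#'   electrodes.
#' @export
instantaneous_phase <- function(stack) {
  stopifnot(inherits(stack, "snapshot_stack"))
  nf <- n_frames(stack)
  if (nf < 8) stop("need at least 8 frames for the analytic signal")
  X <- t(as_channel_matrix(stack))              # time x channels
  v <- apply(X, 2, stats::var)
  degen <- v <= 0 | !is.finite(v)
  ph <- matrix(0, nrow(X), ncol(X))
  if (any(!degen)) {
    Z <- analytic_signal(sweep(X[, !degen, drop = FALSE], 2,
                               colMeans(X[, !degen, drop = FALSE])))
    ph[, !degen] <- wrap_phase(Arg(Z))
  }
  d <- dim(stack$frames)
  out <- snapshot_stack(array(t(ph), dim = d), stack$frame_interval,
                        stack$window)
  out$degenerate <- matrix(degen, d[1], d[2])
  class(out) <- c("phase_stack", class(out))
  out
}

#' Phase-gradient vector field between two phase maps
#'
#' The standard phase-wave velocity `v = -(dphi/dt) grad(phi) / |grad(phi)|^2`
#' evaluated between the phase maps at `t` and `t + lag` (default 10 ms):
#' `dphi` is the wrapped phase difference across the lag and `grad(phi)` the
#' wrapped central-difference spatial gradient.  Vectors are expressed in
#' grid units per second in the flipped-y frame (`vx` along columns, `vy`
#' upward), so the vector angle is directly comparable to propagation
#' direction angles.  Electrodes whose spatial gradient is below `tol` are
#' returned as zero vectors and flagged degenerate.
#'
#' @param phases a `phase_stack` from [instantaneous_phase()].
#' @param t time of the first map in s (from the start of the stack).
#' @param lag lag in s (default 0.010).
#' @param tol minimum gradient magnitude (rad/grid unit).
#' @param smooth_sigma Gaussian smoothing of the phase maps in grid units
#'   before differencing, applied in the complex domain (`exp(i phi)`) so
#'   wrapping is respected; 0 disables.  Mild smoothing (the default 1)
#'   suppresses per-electrode phase noise that would otherwise scatter the
#'   gradient directions.
#' @return A list of class `vector_field`: matrices `vx`, `vy`, logical
#'   `degenerate`, plus `t` and `lag`.
#' @export
vector_field <- function(phases, t = 0, lag = 0.010, tol = 1e-6,
                         smooth_sigma = 1) {
  stopifnot(inherits(phases, "phase_stack"))
  dt <- phases$frame_interval
  i1 <- round(t / dt) + 1L
  i2 <- round((t + lag) / dt) + 1L
  nf <- n_frames(phases)
  if (i1 < 1 || i2 > nf || i2 <= i1)
    stop("t and t + lag must lie within the stack")
  p1 <- smooth_phase_map(get_frame(phases, i1), smooth_sigma)
  p2 <- smooth_phase_map(get_frame(phases, i2), smooth_sigma)
  dphi <- wrap_phase(p2 - p1) / ((i2 - i1) * dt)
  g <- phase_gradient(p1)
  g2 <- g$gx^2 + g$gy^2
  degen <- g2 < tol^2
  g2[degen] <- 1
  vx <- -dphi * g$gx / g2
  vy <- -dphi * g$gy / g2
  vx[degen] <- 0; vy[degen] <- 0
  structure(list(vx = vx, vy = vy, degenerate = degen, t = t, lag = lag),
            class = "vector_field")
}

## Gaussian smoothing of a wrapped phase map via the unit-circle embedding;
## reflection-free periodic smoothing is fine at these small sigmas
smooth_phase_map <- function(p, sigma) {
  if (sigma <= 0) return(p)
  z <- smooth_field_2d(cos(p), sigma) + 1i * smooth_field_2d(sin(p), sigma)
  Arg(z)
}

## wrapped central-difference gradient of a phase map; gx along columns,
## gy in the flipped-y (upward) direction; one-sided at borders
phase_gradient <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3)
    gx[, 2:(nc - 1)] <- wrap_phase(p[, 3:nc] - p[, 1:(nc - 2)]) / 2
  gx[, 1] <- wrap_phase(p[, 2] - p[, 1])
  gx[, nc] <- wrap_phase(p[, nc] - p[, nc - 1])
  ## row index increases downward; flipped-y gradient is the negative row diff
  if (nr >= 3)
    gy[2:(nr - 1), ] <- -wrap_phase(p[3:nr, ] - p[1:(nr - 2), ]) / 2
  gy[1, ] <- -wrap_phase(p[2, ] - p[1, ])
  gy[nr, ] <- -wrap_phase(p[nr, ] - p[nr - 1, ])
  list(gx = gx, gy = gy)
}

#' Vector-field angles
#'
#' @param vf a [vector_field()].
#' @return vector of angles (radians) of non-degenerate vectors.
#' @export
vector_field_angles <- function(vf) {
  ok <- !vf$degenerate
  atan2(vf$vy[ok], vf$vx[ok])
}

#' Winding number of a phase map around a point
#'
#' Accumulates wrapped phase increments along a discrete circle around
#' `center` and divides by `2 pi`.  The circle is traversed
#' counter-clockwise in raw array coordinates (y = row index, increasing
#' downward); under the package's flipped-y angle convention a
#' counter-clockwise-rotating spiral (`m > 0`) then yields winding `+m`, so
#' positive winding = CCW rotation and negative = CW.  Phases are
#' interpolated bilinearly on the unit circle (via `exp(i phi)`) to respect
#' wrapping.
#'
#' @param phase_map matrix of phases in radians.
#' @param center `(row, col)` centre (fractional allowed).
#' @param radius circle radius in grid units (>= 2); the circle must lie
#'   within the grid.
#' @param n_samples points on the circle (default `max(16, 8 * radius)`).
#' @return signed integer winding number.
#' @export
winding_number <- function(phase_map, center, radius,
                           n_samples = max(16L, round(8 * radius))) {
  if (radius < 2) stop("radius must be >= 2 grid units")
  nr <- nrow(phase_map); nc <- ncol(phase_map)
  beta <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  rr <- center[1] + radius * sin(beta)
  cc <- center[2] + radius * cos(beta)
  if (any(rr < 1) || any(rr > nr) || any(cc < 1) || any(cc > nc))
    stop("circle of given radius does not fit in the grid")
  ph <- interp_phase(phase_map, rr, cc)
  total <- sum(wrap_phase(diff(c(ph, ph[1]))))
  as.integer(round(total / (2 * pi)))
}

## bilinear interpolation of a wrapped phase field at fractional positions
interp_phase <- function(p, rr, cc) {
  z <- exp(1i * p)
  r0 <- pmin(pmax(floor(rr), 1), nrow(p) - 1)
  c0 <- pmin(pmax(floor(cc), 1), ncol(p) - 1)
  fr <- rr - r0; fc <- cc - c0
  idx <- function(r, c) z[cbind(r, c)]
  zi <- (1 - fr) * (1 - fc) * idx(r0, c0) +
    (1 - fr) * fc * idx(r0, c0 + 1) +
    fr * (1 - fc) * idx(r0 + 1, c0) +
    fr * fc * idx(r0 + 1, c0 + 1)
  Arg(zi)
}
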