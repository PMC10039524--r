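test_that("instantaneous phase tracks the analytic signal", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  st <- snapshot_stack(array(rbind(cos(2 * pi * 2 * t),
                                   sin(2 * pi * 2 * t),
                                   rep(0, length(t)),
                                   cos(2 * pi * 2 * t)),
                             c(2, 2, length(t))),
                       frame_interval = 1 / fs)
  expect_warning(ph <- instantaneous_phase(st), NA)
  # unwrapped slope ~ 2 pi f = 4 pi rad/s away from the edges
  tr <- ph$frames[1, 1, ]
  un <- cumsum(c(tr[1], wrap_phase(diff(tr))))
  sel <- 200:1800
  slope <- coef(lm(un[sel] ~ t[sel]))[[2]]
  expect_equal(slope, 4 * pi, tolerance = 0.02)
  # sin lags cos by pi/2 at every interior frame
  dphi <- wrap_phase(ph$frames[1, 1, sel] - ph$frames[2, 1, sel])
  expect_lt(max(abs(dphi - pi / 2)), 0.05)
  # constant trace is flagged degenerate with phase 0
  expect_true(ph$degenerate[1, 2])
  expect_true(all(ph$frames[1, 2, ] == 0))
  expect_error(instantaneous_phase(subset_frames(st, 1:5)), "8 frames")
})

test_that("spiral phase maps equal the programmed angular field", {
  st <- clean_spiral_stack()
  ph <- instantaneous_phase(st)
  pm <- get_frame(ph, 130)
  # programmed field: m * beta + k * rho + const (array coordinates)
  beta <- atan2(lay32$row - 16, lay32$col - 16)
  rho <- sqrt((lay32$row - 16)^2 + (lay32$col - 16)^2) * 42
  expected <- beta + 2 * pi / 1200 * rho
  d <- sqrt((lay32$row - 16)^2 + (lay32$col - 16)^2)
  off_core <- d > 4 & d < 12
  resid <- wrap_phase(as.vector(pm)[off_core] - expected[off_core])
  resid <- wrap_phase(resid - circ_mean(resid))
  expect_lt(sqrt(mean(resid^2)), 0.2)
})

test_that("vector fields point along propagation and rotate around cores", {
  # planar: angles within 0.1 rad of the programmed direction
  ph <- instantaneous_phase(planar_stack(seed = 2, angle = 1.1, noise_sd = 0))
  ang <- vector_field_angles(vector_field(ph, 0.4, 0.012))
  expect_lt(abs(circ_mean(ang) - 1.1), 0.1)

  # spiral with zero radial wavenumber: pure rotation, vectors tangential
  # (near-orthogonal to the radial direction)
  p0 <- spiral_params(center = c(16, 16), frequency = 2, m = 1L,
                      cycles = 2L, wavenumber = 0, noise_sd = 0,
                      frame_rate = 250, seed = 2)
  ph0 <- instantaneous_phase(extract_snapshots(
    generate_spiral_wave(p0, lay32), frame_interval = 1 / 250))
  vf0s <- vector_field(ph0, 0.4, 0.012)
  d <- sqrt((lay32$row - 16)^2 + (lay32$col - 16)^2)
  ok <- !vf0s$degenerate & matrix(d > 5 & d < 12, 32, 32)
  radial <- matrix(atan2(-(lay32$row - 16), lay32$col - 16), 32, 32)
  vang <- atan2(vf0s$vy, vf0s$vx)
  cosr <- abs(cos(vang[ok] - radial[ok]))
  expect_lt(mean(cosr), 0.2)

  # default spiral: vector angles match the programmed gradient geometry.
  # With phase ~ m*beta + k*rho the phase grows outward, so propagation is
  # inward-tilted: v points along -grad(phi), i.e. at angle
  # radial + atan2(m/rho, -k) from the outward radial direction.
  phs <- instantaneous_phase(clean_spiral_stack())
  vf <- vector_field(phs, 0.4, 0.012)
  okd <- !vf$degenerate & matrix(d > 6 & d < 11, 32, 32)
  k_px <- 2 * pi / 1200 * 42
  expected <- radial[okd] + atan2(1 / matrix(d, 32, 32)[okd], -k_px)
  vangd <- atan2(vf$vy, vf$vx)
  err <- wrap_phase(vangd[okd] - expected)
  expect_lt(mean(abs(err)), 0.2)

  # static phases give an all-zero field
  stat <- snapshot_stack(array(rep(matrix(runif(256), 16, 16), 20),
                               c(16, 16, 20)), frame_interval = 0.004)
  class(stat) <- c("phase_stack", class(stat))
  vf0 <- vector_field(stat, 0, 0.012)
  expect_true(all(vf0$vx == 0) && all(vf0$vy == 0))
})

test_that("winding numbers obey the canonical identities", {
  # canonical singularity: phi = atan2(y - yc, x - xc) -> +1
  beta <- matrix(atan2(row(matrix(0, 21, 21)) - 11,
                       col(matrix(0, 21, 21)) - 11), 21, 21)
  expect_equal(winding_number(beta, c(11, 11), 6), 1L)
  expect_equal(winding_number(-beta, c(11, 11), 6), -1L)
  # planar field has no singularity
  plane <- matrix(0.4 * col(matrix(0, 21, 21)), 21, 21)
  expect_equal(winding_number(wrap_phase(plane), c(11, 11), 6), 0L)
  # rotating the map by 90 degrees preserves the winding number
  rot90 <- t(beta)[, 21:1]
  expect_equal(winding_number(rot90, c(11, 11), 6), 1L)
  # mirroring negates it
  expect_equal(winding_number(beta[, 21:1], c(11, 11), 6), -1L)
  expect_error(winding_number(beta, c(11, 11), 1), "radius")
  expect_error(winding_number(beta, c(2, 2), 6), "fit")
})
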