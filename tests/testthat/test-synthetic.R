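test_that("spiral generator satisfies its programmed geometry", {
  st <- clean_spiral_stack()
  ph <- instantaneous_phase(st)

  # a +1-arm spiral carries winding number +1 around its core
  expect_equal(winding_number(get_frame(ph, 130), c(16, 16), 6), 1L)

  # amplitude dip: |v| near the core is well below the surrounding annulus
  absmean <- rowMeans(abs(as_channel_matrix(st)))
  d <- sqrt((lay32$row - 16)^2 + (lay32$col - 16)^2)
  expect_lt(mean(absmean[d < 1.5]), mean(absmean[d >= 9 & d <= 15]))

  # phase at an off-centre electrode advances by ~ cycles * 2 pi;
  # the slope of the unwrapped phase equals 2 pi f
  p <- spiral_params(center = c(16, 16), frequency = 2, m = 1L, cycles = 4L,
                     duration = 2, noise_sd = 0, frame_rate = 250, seed = 1L)
  ph4 <- instantaneous_phase(
    extract_snapshots(generate_spiral_wave(p, lay32), frame_interval = 1 / 250))
  tr <- ph4$frames[16, 24, ]
  un <- cumsum(c(tr[1], wrap_phase(diff(tr))))
  sel <- 50:450   # clear of analytic-signal edges
  slope <- coef(lm(un[sel] ~ sel))[[2]] * 250
  expect_equal(slope, 2 * pi * 2, tolerance = 0.02)

  # full-window advance corresponds to ~4 cycles
  expect_equal(count_cycles(ph4, c(16, 16)), 4L)
})

test_that("spiral generator rejects invalid parameters", {
  expect_error(spiral_params(frequency = 2, cycles = 5L, duration = 1),
               "cycles")
  expect_error(spiral_params(frame_rate = 3, frequency = 2), "Nyquist")
  expect_error(generate_spiral_wave(
    spiral_params(center = c(40, 8), frame_rate = 250), lay32), "outside")
})

test_that("planar waves have aligned gradients and no singularity", {
  st <- planar_stack(seed = 3, angle = 0.7, noise_sd = 0)
  ph <- instantaneous_phase(st)
  vf <- vector_field(ph, 0.4, 0.012)
  ang <- vector_field_angles(vf)
  expect_gt(resultant_length(ang), 0.95)
  expect_equal(winding_number(get_frame(ph, 130), c(16, 16), 6), 0L)

  # antiparallel propagation for alpha = 0 vs alpha = pi
  st0 <- planar_stack(seed = 3, angle = 0, noise_sd = 0)
  stpi <- planar_stack(seed = 3, angle = pi, noise_sd = 0)
  a0 <- vector_field_angles(vector_field(instantaneous_phase(st0), 0.4, 0.012))
  api <- vector_field_angles(vector_field(instantaneous_phase(stpi), 0.4, 0.012))
  dmean <- Arg(mean(exp(1i * a0)) * Conj(mean(exp(1i * api))))
  expect_lt(abs(abs(dmean) - pi), 0.1)
})

test_that("baseline correlation structure follows its parameters", {
  lay8 <- electrode_layout(8, 8, 42)
  # vanishing correlation length: independent electrodes
  b0 <- generate_baseline(noise_sd = 5, spatial_corr_length = 0,
                          temporal_corr = 0, duration = 2, frame_rate = 1000,
                          seed = 5, layout = lay8)
  C0 <- cor(t(b0$voltage))
  expect_lt(abs(mean(C0[upper.tri(C0)])), 0.05)

  # correlation length far beyond the array: near-common signal
  b1 <- generate_baseline(noise_sd = 5, spatial_corr_length = 42 * 40,
                          temporal_corr = 0, duration = 1, frame_rate = 500,
                          seed = 5, layout = lay8)
  C1 <- cor(t(b1$voltage))
  expect_gt(mean(C1[upper.tri(C1)]), 0.9)

  # determinism
  b2 <- generate_baseline(duration = 0.5, frame_rate = 250, seed = 9,
                          layout = lay8)
  b3 <- generate_baseline(duration = 0.5, frame_rate = 250, seed = 9,
                          layout = lay8)
  expect_identical(b2$voltage, b3$voltage)
})

test_that("generators are deterministic under a fixed seed", {
  p <- spiral_params(center = c(8, 8), frame_rate = 250, seed = 11L)
  r1 <- generate_spiral_wave(p, lay16)
  r2 <- generate_spiral_wave(p, lay16)
  expect_identical(r1$voltage, r2$voltage)
  w1 <- generate_planar_wave(1, 2, duration = 0.5, frame_rate = 250,
                             seed = 4, layout = lay16)
  w2 <- generate_planar_wave(1, 2, duration = 0.5, frame_rate = 250,
                             seed = 4, layout = lay16)
  expect_identical(w1$voltage, w2$voltage)
})

test_that("dataset assembly books events faithfully", {
  lay8 <- electrode_layout(8, 8, 42)
  spec <- dataset_spec(n_spiral_cw = 5, n_spiral_ccw = 5, gap_s = 0.5,
                       duration_mean = 0.8, duration_sd = 0.1,
                       duration_min = 0.6, frame_rate = 100)
  ds <- generate_dataset(spec, seed = 2, layout = lay8)
  gt <- ds$ground_truth
  expect_equal(nrow(gt), 10)
  expect_equal(sum(gt$direction == "CW"), 5)
  expect_equal(sum(gt$direction == "CCW"), 5)
  # windows disjoint and inside the recording
  expect_true(all(gt$start_s[-1] >= head(gt$end_s, -1)))
  expect_true(all(gt$end_s <= recording_duration(ds$recording)))

  # empty spec: pure baseline
  ds0 <- generate_dataset(dataset_spec(n_spiral_cw = 0, n_spiral_ccw = 0,
                                       gap_s = 1, frame_rate = 100),
                          seed = 2, layout = lay8)
  expect_equal(nrow(ds0$ground_truth), 0)

  # duration sampler concentrates at its programmed mean
  set.seed(31)
  dur <- spiralmea:::rtruncnorm_lower(200, 2.52, 1.0, 0.6)
  expect_lt(abs(mean(dur) - 2.52), 0.2)
})

test_that("additive Gaussian noise behaves element-wise", {
  st <- snapshot_stack(array(rnorm(64 * 64 * 6), c(64, 64, 6)))
  expect_identical(add_gaussian_noise(st, 0, 0)$frames, st$frames)
  shifted <- add_gaussian_noise(st, 3.5, 0)
  expect_equal(shifted$frames, st$frames + 3.5)
  noisy <- add_gaussian_noise(st, 0, 10, seed = 8)
  expect_equal(sd(noisy$frames - st$frames), 10, tolerance = 0.05)
  # determinism
  expect_identical(add_gaussian_noise(st, 0, 10, seed = 8)$frames,
                   noisy$frames)
})
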