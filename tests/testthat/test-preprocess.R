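test_that("Butterworth band-pass has the designed frequency response", {
  des <- butter_bandpass(1, 4, 1000, 2)
  # oracle: evaluate |H| directly on the unit circle
  expect_gte(filter_gain(des$b, des$a, 2, 1000), 0.9)
  expect_lte(filter_gain(des$b, des$a, 40, 1000), 0.05)
  expect_error(butter_bandpass(1, 600, 1000), "Nyquist|band edges")
})

test_that("zero-phase filtering preserves phase and passes the band", {
  fs <- 250
  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t)
  rec <- voltage_recording(matrix(rep(x, each = 4), nrow = 4), fs,
                          electrode_layout(2, 2, 42))
  out <- bandpass_delta(rec)
  y <- out$voltage[1, ]
  core <- (fs + 1):(5 * fs)
  # amplitude gain near unity in the passband
  expect_gt(sd(y[core]) / sd(x[core]), 0.9)
  # zero group delay: cross-correlation peak at lag 0
  cc <- ccf(y[core], x[core], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # linearity: zero in, zero out
  zero <- voltage_recording(matrix(0, 4, 1500), fs, electrode_layout(2, 2, 42))
  expect_equal(max(abs(bandpass_delta(zero)$voltage)), 0)
})

test_that("filtering is idempotent up to tolerance", {
  # content concentrated mid-band (a 2 Hz wave), where the gentle
  # second-order response is flat; near the -3 dB edges idempotence
  # cannot hold for any Butterworth design
  rec <- generate_spiral_wave(
    spiral_params(center = c(8, 8), frequency = 2, cycles = 10L,
                  duration = 6, noise_sd = 0, frame_rate = 250, seed = 2),
    electrode_layout(16, 16, 42))
  once <- bandpass_delta(rec)
  twice <- bandpass_delta(once)
  core <- 126:1375                 # interior, clear of edge transients
  rel <- sqrt(mean((twice$voltage[, core] - once$voltage[, core])^2)) /
    sqrt(mean(once$voltage[, core]^2))
  expect_lt(rel, 0.05)
})

test_that("artifact removal follows the replacement rule", {
  lay1 <- electrode_layout(1, 1, 42)
  rec <- voltage_recording(matrix(c(1, 5, 300, 3), 1), 100, lay1)
  out <- remove_artifacts(rec, 200)
  expect_equal(out$voltage[1, ], c(1, 5, 3, 3))  # mean(1, 5, 3) = 3

  # identity when nothing exceeds the threshold
  rec2 <- voltage_recording(matrix(c(-150, 20, 199), 1), 100, lay1)
  expect_identical(remove_artifacts(rec2, 200)$voltage, rec2$voltage)

  # an all-artifact channel is zeroed with a warning
  rec3 <- voltage_recording(matrix(500, 1, 4), 100, lay1)
  expect_warning(out3 <- remove_artifacts(rec3, 200), "entirely artifacts")
  expect_equal(out3$voltage[1, ], rep(0, 4))

  # never increases max |v|, never touches sub-threshold samples
  lay4 <- electrode_layout(2, 2, 42)
  v <- matrix(rnorm(4 * 200, 0, 120), 4)
  rec4 <- voltage_recording(v, 100, lay4)
  out4 <- remove_artifacts(rec4, 200)
  expect_lte(max(abs(out4$voltage)), max(abs(v)))
  sub <- abs(v) <= 200
  expect_identical(out4$voltage[sub], v[sub])
})

test_that("snapshot extraction bins and reshapes correctly", {
  lay4 <- electrode_layout(2, 2, 42)
  # 7.7 kHz -> 1 ms bins of 7 or 8 samples; 2.5 s window -> 2500 frames
  fs <- 7700
  rec <- voltage_recording(matrix(rnorm(4 * fs * 2.5), 4), fs, lay4)
  st <- extract_snapshots(rec, c(0, 2.5), 0.001)
  expect_equal(n_frames(st), 2500)
  spp <- diff(floor((0:2500) * fs * 0.001))
  expect_true(all(spp %in% c(7, 8)))

  # frame_interval = 1/fs: identity resampling
  rec2 <- voltage_recording(matrix(rnorm(4 * 100), 4), 100, lay4)
  st2 <- extract_snapshots(rec2, frame_interval = 1 / 100)
  expect_equal(as_channel_matrix(st2), rec2$voltage)

  # constant input -> constant frames; integer binning conserves the mean
  rec3 <- voltage_recording(matrix(7.25, 4, 100), 100, lay4)
  st3 <- extract_snapshots(rec3, frame_interval = 0.02)
  expect_true(all(st3$frames == 7.25))
  rec4 <- voltage_recording(matrix(rnorm(4 * 120), 4), 120, lay4)
  st4 <- extract_snapshots(rec4, frame_interval = 1 / 12)
  expect_equal(mean(st4$frames), mean(rec4$voltage), tolerance = 1e-12)

  expect_error(extract_snapshots(rec2, c(0.5, 0.5), 0.01), "window")
})

test_that("evenly spaced selection hits the documented indices", {
  st <- snapshot_stack(array(seq_len(2501), c(1, 1, 2501)))
  sel <- select_evenly_spaced(st, 6)
  expect_equal(as.vector(sel$frames), c(1, 501, 1001, 1501, 2001, 2501))
  # k equal to the frame count is the identity
  st6 <- snapshot_stack(array(1:6, c(1, 1, 6)))
  expect_equal(as.vector(select_evenly_spaced(st6, 6)$frames), 1:6)
  expect_error(select_evenly_spaced(st6, 1), "k")
  expect_error(select_evenly_spaced(st6, 7), "fewer")
})

test_that("band table separates frequency bands", {
  fs <- 250
  lay4 <- electrode_layout(2, 2, 42)
  t <- (0:(6 * fs - 1)) / fs
  rec <- voltage_recording(matrix(rep(sin(2 * pi * 2 * t), each = 4), 4),
                           fs, lay4)
  tab <- band_amplitudes(rec)
  expect_equal(nrow(tab), 5)
  delta <- tab$amplitude[tab$band == "delta"]
  expect_true(all(delta > 10 * tab$amplitude[tab$band != "delta"]))

  # white noise leaves every band strictly positive
  recn <- voltage_recording(matrix(rnorm(4 * 6 * fs), 4), fs, lay4)
  expect_true(all(band_amplitudes(recn)$amplitude > 0))

  # a synthetic spiral concentrates amplitude in delta
  sp <- generate_spiral_wave(spiral_params(center = c(8, 8),
                                           frame_rate = 250), lay16)
  tsp <- band_amplitudes(sp)
  expect_equal(tsp$band[which.max(tsp$amplitude)], "delta")

  # bands above Nyquist are dropped with a warning
  slow <- voltage_recording(matrix(rnorm(4 * 500), 4), 50, lay4)
  expect_warning(tab2 <- band_amplitudes(slow), "Nyquist")
  expect_false("gamma" %in% tab2$band)
})
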