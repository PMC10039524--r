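# shared fixtures: small grids and cached snapshot stacks keep the suite
# inside its time budget; everything is generated in code under fixed seeds

lay16 <- electrode_layout(16, 16, 42)
lay32 <- electrode_layout(32, 32, 42)

# a clean (noise-free) mid-grid spiral at 250 Hz and its phases
clean_spiral_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- spiral_params(center = c(16, 16), frequency = 2, m = 1L,
                         cycles = 2L, noise_sd = 0, frame_rate = 250,
                         seed = 42L)
      cache <<- extract_snapshots(generate_spiral_wave(p, lay32),
                                  frame_interval = 1 / 250)
    }
    cache
  }
})

# default-noise spiral stack used by classification tests
noisy_spiral_stack <- function(seed = 1L, m = 1L, cycles = 2L,
                               center = c(16, 16), noise_sd = 10) {
  p <- spiral_params(center = center, frequency = 2, m = m, cycles = cycles,
                     noise_sd = noise_sd, frame_rate = 250, seed = seed)
  extract_snapshots(generate_spiral_wave(p, lay32), frame_interval = 1 / 250)
}

planar_stack <- function(seed = 1L, angle = 0, noise_sd = 10,
                         duration = 1.05) {
  rec <- generate_planar_wave(angle, 2, noise_sd = noise_sd,
                              duration = duration, frame_rate = 250,
                              seed = seed, layout = lay32)
  extract_snapshots(rec, frame_interval = 1 / 250)
}

baseline_stack <- function(seed = 1L, duration = 1.05, ...) {
  rec <- generate_baseline(duration = duration, frame_rate = 250,
                           seed = seed, layout = lay32, ...)
  extract_snapshots(rec, frame_interval = 1 / 250)
}

# tiny 16x16 single-plane training set for adversarial-model tests
smoke_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      snaps <- lapply(1:34, function(s) {
        p <- spiral_params(center = c(6, 10), frequency = 2, m = 1L,
                           cycles = 1L, frame_rate = 250, seed = s,
                           domain_radius = 300, dip_radius = 120,
                           wavenumber = 2 * pi / 800)
        st <- extract_snapshots(generate_spiral_wave(p, lay16),
                                frame_interval = 1 / 250)
        select_evenly_spaced(st, 6)$frames
      })
      cache <<- build_training_set(array(unlist(snaps), c(16, 16, 204)))
    }
    cache
  }
})
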