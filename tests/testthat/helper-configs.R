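# Small phantom geometries shared across tests: full 50 mm field of view at
# reduced matrix so voxel counts stay manageable.
small_phantom <- function(n_phases = 4L, nx = 64L, r_ed = 4.2, r_es = 2.2,
                          myo_volume = 700) {
  phantom_config(nx = nx, ny = nx, dx = 50 / nx, dy = 50 / nx,
                 n_slices = 10L, dz = 1.25, n_phases = n_phases,
                 r_ed = r_ed, r_es = r_es, myo_volume = myo_volume,
                 base_slice = 2L, apex_slice = 9L)
}

# one noisy small phantom with its ROIs, built once per test file use
noisy_small_phantom <- function(sigma = 0.25, seed = 11L, ...) {
  ph <- generate_phantom(small_phantom(...))
  rois <- rois_from_truth(ph$truth, bg_size = 16L)
  noisy <- add_rician_noise(ph$series, sigma, seed = seed)
  list(phantom = ph, rois = rois, noisy = noisy, sigma = sigma)
}
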