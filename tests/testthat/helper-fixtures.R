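# Shared small fixtures.  Source discretization is reduced from the
# 40000-point default where a coarser bowl keeps unit tests fast without
# touching the physics being asserted.

fast_geom <- function(n = 6000) transducer_geometry(source_discretization = n)

# a small noiseless thermometry series with a centred Gaussian deposit
heated_series <- function(grid = grid3d(17, 17, 9, 1e-3, 1e-3, 2e-3),
                          peak = 5, n_frames = 4, snr = Inf, seed = 1,
                          seq = sequence_constants(),
                          sigma = c(2e-3, 2e-3, 3e-3),
                          deposit_time = seq$frame_interval) {
  heating <- heating_model(peak_delta_T = peak, gaussian_sigma = sigma,
                           deposit_time = deposit_time)
  simulate_mrti_series(grid, n_frames = n_frames, heating = heating,
                       snr = snr, seq = seq, seed = seed)
}

# temperature series with given constant frames (degC rise) and interval
const_temp_series <- function(delta_T_values, frame_interval_s, baseline,
                              dims = c(2, 2, 2), spacing = 1e-3) {
  g <- grid3d(dims[1], dims[2], dims[3], spacing)
  frames <- lapply(delta_T_values, function(v) array(v, dim = dims))
  structure(list(delta_T = frames, baseline_temperature = baseline,
                 mask = NULL, grid = g, frame_interval = frame_interval_s),
            class = "temperature_series")
}
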