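# Shared small synthetic scenes for unit tests. All noiseless unless noted.

tiny_params <- function(n_frames = 16, fov = c(48, 48), n_z = 6, seed = 5, ...) {
  acquisition_params(fov_px = fov, n_frames = n_frames, n_z = n_z,
                     seed = seed, ...)
}

resting_cell_movie <- function(n_frames = 12, speed = 4, seed = 5, ...) {
  p <- tiny_params(n_frames = n_frames, seed = seed, ...)
  cl <- cell_spec(1, center_um = c(16, 16), speed_um_min = speed)
  list(bundle = render_movie(list(cl), list(), list(), p, seed = seed),
       params = p, cell = cl)
}

sparkle_movie <- function(start = 5, duration = 2, peak = 800, seed = 5,
                          n_frames = 16, speed = 4) {
  p <- tiny_params(n_frames = n_frames, seed = seed)
  cl <- cell_spec(1, center_um = c(16, 16), speed_um_min = speed)
  ev <- ca_event_spec("local", 1, start, duration, peak, offset_um = c(2.4, 0))
  list(bundle = render_movie(list(cl), list(ev), list(), p, seed = seed),
       params = p, cell = cl, event = ev)
}
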