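# Shared fixture builders. Everything is generated in code; no binary data.

default_md <- function(n_frames = 1L, n_z = 5L, height = 64L, width = 64L,
                       pixel_size_xy = 0.2, z_step = 1.0,
                       frame_interval = 1.5) {
  acquisition_metadata(pixel_size_xy = pixel_size_xy, z_step = z_step,
                       frame_interval = frame_interval, n_frames = n_frames,
                       n_z = n_z, height = height, width = width)
}

quiet_imaging <- function(...) {
  imaging_params(noise_model = list(type = "none"), bleach_rate = 0, ...)
}

# noiseless single-blob volume with the blob at position pos (um)
blob_volume <- function(pos = c(6.4, 6.4, 2), md = default_md(),
                        params = quiet_imaging()) {
  render_frame(matrix(pos, 1L, 3L), params, md)
}

# straight-line trajectory along +x at constant speed (um/s)
line_traj <- function(speed, n = 40L, dt = 1.5, id = 1L, x0 = 0) {
  trajectory(track_id = id, frame = seq_len(n),
             x_um = x0 + speed * dt * (seq_len(n) - 1L), dt = dt)
}

# alternating square-wave positions 0, d, 0, d, ... along x
square_wave_traj <- function(d = 0.3, n = 32L, dt = 1.5, id = 1L) {
  trajectory(track_id = id, frame = seq_len(n),
             x_um = d * (seq_len(n) %% 2L == 0L), dt = dt)
}
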