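# Demonstration pipeline configuration: a small noise-free scene whose
# detected sparkle count equals the ground-truth count.
seed: 7
output_dir: casparkle_demo
acquisition:
  fov_px: [64, 64]
  n_frames: 24
  pixel_size_um: 0.684
  z_step_um: 4
  n_z: 6
  frame_interval_s: 5
  photon_scale: .inf
  read_noise_sd: 0
  background_counts: 0
  bit_depth: 16
scene:
  n_cells: 2
  n_sparkles: 5
  n_cellwide: 1
  n_autofluor: 0
  sparkle_peak_ca_nM: 800
  cellwide_peak_ca_nM: 800
  cell:
    speed_um_min: 4
preprocess:
  red_scale: 0.2
detection:
  local_thresh_sd: 5.4
  cellwide_thresh_sd: 2.1
  local_min_area_um2: 1.4
  cellwide_min_area_um2: 25
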