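# Demonstration pipeline: synthetic 8-channel phantom, 3D shells
# excitation of a 60 mm cube, phase-relaxed design with re-VERSE, Bloch
# verification and spatially resolved EPG echo prediction. Problem sizes
# are reduced (coarse grid, short trajectory) so the whole pipeline runs
# in a few minutes on one CPU.
seed: 1
maps:
  grid_shape: [20, 20, 20]
  fov_mm: 220
  n_channels: 8
  b0_amplitude_hz: 40
target:
  shape: cube
  size_mm: 60
  apodization_fwhm_mm: 6
  flip_deg: 90
trajectory:
  type: shells_3d
  n_shells: 4
  k_max: 160
  radial_undersample: 1.75
  angular_undersample: 3.21
  inter_shell_rotation: 30
  fov_mm: 220
design:
  w_r: 0.25
  lambda: 0.01
  peak_ut: 11
  attenuation_ut: 8
  g_max: 40
  s_max: 200
  dt: 0.0000128
  design_res_mm: 11
  time_decimation: 4
  max_iter: 5
  use_girf: true
sequence:
  asymptotic_angle: 35
  n_echoes: 100
  esp: 4
  tissue: csf
  n_dummy: 6
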