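# Demo pipeline configuration: a pair of parallel membranes 300 nm apart,
# imaged for 120 frames, localized, quality-checked, density-rendered and
# registered onto a synthetic TEM-like image of the same structure.
seed: 42
output_dir: smlmpipe_demo
simulate:
  structure:
    kind: membrane_pair
    params:
      spacing_nm: 300
      linear_density_um: 80
      length_nm: 3000
  field_of_view: [4000, 4000]
  n_frames: 120
  background: 2
  switching:
    recovery_rate: 0.5
    mean_on_time_ms: 60
    bleach_prob: 0.5
    photon_range: [100, 1000]
  camera:
    pixel_size_nm: 80
    integration_ms: 50
    fps: 17
  em:
    size: [220, 220]
    scale: 0.05
    rotation_deg: 15
    translation: [40, 10]
    noise_level: 0.01
localize:
  half_window: 10
  threshold: 4
  merge_radius_nm: 100
  min_photons: 80
quality:
  search_radius: 200
  n_epochs: 2
resolution:
  K: 20
render:
  out_pixel_nm: 10
register:
  kind: similarity
  alpha: 0.5
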