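# Demo pipeline: simulate one synthetic nucleolar tomogram with three
# radial shell classes, fit the nucleolar sphere, and run the radial
# statistics. Runs in seconds.
seed: 1
stages:
  simulate: true
  fit_spheres: true
  stats: true
scenario:
  sphere_center: [160.0, 160.0, 160.0]
  sphere_radius: 120.0
  voxel_size: 13.68
  classes:
    - {label: 1, count: 200, shell_mean: 0.85, shell_sd: 0.05}
    - {label: 2, count: 200, shell_mean: 0.95, shell_sd: 0.05}
    - {label: 3, count: 200, shell_mean: 1.00, shell_sd: 0.05}
  background_spectrum: ~
  surface_spike: ~
fit:
  max_iter: 50
  min_inliers: 10
stats:
  n_perm: 2000
  bandwidth: auto
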