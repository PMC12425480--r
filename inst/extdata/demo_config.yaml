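# Demonstration pipeline configuration: a three-thylakoid granum phantom at
# the measured spinach geometry, with hard-core PSII point patterns on the
# appressed membranes. Runs end-to-end in well under a minute on one CPU.
seed: 1
output_dir: granametrics_demo
write_volumes: false
synthetic:
  enabled: true
  n_thylakoids: 3
  granum_radius: 60        # nm
  lamella_length: 60       # nm
  membrane_thickness: 5.1  # nm
  stromal_gap: 3.2         # nm
  lumen_width: 10.8        # nm
  voxel_size: 1.408        # nm (bin4)
  volume_shape: [144, 112, 112]
  noise_sigma: 0.1
  particle_classes:
    - class_label: PSII
      min_separation: 13   # nm
domains:
  threshold: 12            # nm center-to-center
  vote_radius: 30          # nm
  iterations: 1
  curvature_cutoff: 0.1    # nm^-1
morphometry:
  patch_size: 50           # nm
  sample_spacing: 2        # nm
  z_range: 40              # nm
  reference_membrane: 3
particles:
  bin_nm: 10
  source_class: PSII
  target_class: PSII
occupancy:
  footprints: [C2, C2S2, C2S2M2]
  resolution: 0.5          # nm
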