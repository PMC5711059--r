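# Full default configuration of the arcqa QA experiment.
# `arcqa run --config <this file> --out dir/` reproduces the default study.

# one seed = one synthetic "patient" arc plan
seeds: [1, 2, 3, 4, 5, 6, 7, 8]

# systematic MLC perturbation: 1 mm (0.1 cm), bank A, all open leaves
offset_cm: 0.1
bank: A

# grids (cm): fine simulation lattice and the 3 mm analysis lattice
sim_spacing_cm: 0.05
analysis_spacing_cm: 0.3
half_extent_cm: 13.5

# Gaussian penumbra width applied to accumulated fluence (cm)
penumbra_sigma_cm: 0.3

# detector sampling per delivery arm: the GS arm is imaged at fine
# resolution and analyzed on the 3 mm grid; the CS arms are sampled by the
# 729-chamber array (1 cm pitch, 0.5 cm volume average)
gs_detector: analysis3mm
cs_detector: array729

# percent-difference comparison (Van Dyk global normalization)
comparison:
  normalization: global
  low_dose_cutoff_fraction: 0.10
  target_match_fraction: 0.95

# gamma criteria evaluated on the CS rotational pair
gamma_criteria:
  - {dose_diff_percent: 2, distance_mm: 2}
  - {dose_diff_percent: 3, distance_mm: 3}

# synthetic plan generator overrides (empty = package defaults: 72 control
# points over -170..170 degrees, 40 x 1 cm leaf pairs, 6 cm mean aperture)
generator: {}
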