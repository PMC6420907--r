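# Scenario 3: H&E-like melanoma sections for tumor-nuclei detection.
# Patch-based tumor nuclei in 10 of 11 fast-marching regions; tumor cell
# bodies grown from the nuclei by fast marching and textured with patch
# mosaics (one of three cohorts per cell); a blood vessel with bordering
# connective tissue in 1 region; immune cells with moderate overlap. The
# ground truth marks the visible part of the tumor nuclei.
scenario: 3
size: [300, 300]
rules:
  type: visible
  category: tumor_nucleus
  occluders: [immune_cell]
background:
  mean_color: [0.93, 0.87, 0.90]
  color_sd: 0.04
  color_corr: 0.5
regions:
  mode: fast_march
  count: 11
connective:
  border_category: blood_vessel
  n_fields: 2
  interval: [1.5, 4.0]
  blur_sd: 8
  gain: 0.6
  mean_color: [0.93, 0.70, 0.82]
  color_sd: 0.04
libraries:
  nuclei:
    patch_size: 12
    patches_per_cohort: 20
    cohort_means:
      - [0.40, 0.26, 0.50]
      - [0.48, 0.32, 0.58]
      - [0.34, 0.22, 0.44]
    noise_sd: 0.03
  tumor:
    patch_size: 12
    patches_per_cohort: 55
    cohort_means:
      - [0.66, 0.50, 0.74]
      - [0.74, 0.58, 0.80]
      - [0.60, 0.44, 0.68]
    noise_sd: 0.03
  immune:
    patch_size: 12
    patches_per_cohort: 60
    cohort_means:
      - [0.44, 0.34, 0.64]
      - [0.50, 0.40, 0.70]
      - [0.38, 0.28, 0.56]
    noise_sd: 0.03
categories:
  - name: blood_vessel
    shape: region_noise
    region_fill: 1
    mean_color: [0.88, 0.55, 0.58]
    color_sd: 0.05
  - name: tumor_cell
    shape: fast_march_grown
    source: tumor_nucleus
    library: tumor
    growth_per_nucleus: 400
    contour_darken: 0.65
    color_sd: 0.03
  - name: tumor_nucleus
    shape: patch
    region_fill: 10
    attempts_per_region: 8
    library: nuclei
    color_sd: 0.03
  - name: immune_cell
    shape: ellipse
    library: immune
    count: 10
    semi_axes: [5, 10]
    color_sd: 0.03
    overlap: moderate
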