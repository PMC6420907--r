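# Scenario 2: H&E-like melanoma sections with immune-cell-rich regions.
# Tumor cells fill 5 of 7 Voronoi regions, immune cells 2 of 7; connective
# tissue ribbons border the tumor regions. An immune cell enters the
# ground-truth mask when the immune-cell concentration in a 40-pixel
# neighborhood is above 0.2.
scenario: 2
size: [300, 300]
rules:
  type: neighborhood
  cell_category: immune_cell
  target_category: immune_cell
  neighborhood_radius: 40
  concentration_threshold: 0.2
background:
  mean_color: [0.93, 0.86, 0.91]
  color_sd: 0.04
  color_corr: 0.5
regions:
  mode: voronoi
  count: 7
connective:
  border_category: tumor_cell
  n_fields: 3
  interval: [1.5, 5.0]
  blur_sd: 10
  gain: 0.6
  mean_color: [0.93, 0.70, 0.82]
  color_sd: 0.04
categories:
  - name: tumor_cell
    shape: ellipse
    region_fill: 5
    fill_attempts: 60
    semi_axes: [15, 25]
    mean_color: [0.78, 0.62, 0.86]
    color_sd: 0.05
    color_corr: 0.4
    overlap: forbidden
  - name: tumor_nucleus
    shape: ellipse
    parent: tumor_cell
    semi_axes: [3, 10]
    mean_color: [0.48, 0.30, 0.62]
    color_sd: 0.05
    visible_fraction: 0.6
  - name: immune_cell
    shape: ellipse
    region_fill: 2
    fill_attempts: 120
    semi_axes: [4, 8]
    mean_color: [0.42, 0.32, 0.66]
    color_sd: 0.05
    overlap: forbidden
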