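# Scenario 1: immunofluorescence-like melanoma imagery.
# Immune cells (CD45, red), tumor cells (gp100, green), nuclei (DAPI, blue)
# on a dark background. An immune cell enters the ground-truth mask when the
# tumor-cell concentration in a 40-pixel circular neighborhood exceeds 0.3.
scenario: 1
size: [300, 300]
rules:
  type: neighborhood
  cell_category: immune_cell
  target_category: tumor_cell
  neighborhood_radius: 40
  concentration_threshold: 0.3
background:
  mean_color: [0.05, 0.05, 0.12]
  color_sd: 0.05
  color_corr: 0.5
categories:
  - name: hidden_cells            # partially hidden background structures
    shape: ellipse
    count: 15
    semi_axes: [10, 25]
    mean_color: [0.20, 0.25, 0.45]
    blend_to_background: 0.5
    color_sd: 0.05
    overlap: free
  - name: tumor_cell
    shape: ellipse
    count: 25
    semi_axes: [20, 35]
    mean_color: [0.10, 0.65, 0.15]
    color_sd: 0.07
    color_corr: 0.4
    overlap: free
  - name: tumor_nucleus
    shape: ellipse
    parent: tumor_cell
    semi_axes: [8, 12]
    mean_color: [0.45, 0.60, 0.90]
    color_sd: 0.06
    visible_fraction: 0.6
  - name: immune_cell
    shape: ellipse
    count: 20
    semi_axes: [8, 20]
    mean_color: [0.75, 0.12, 0.12]
    color_sd: 0.07
    color_corr: 0.4
    overlap: forbidden
  - name: immune_nucleus
    shape: ellipse
    parent: immune_cell
    semi_axes: [7, 8]
    mean_color: [0.15, 0.20, 0.80]
    color_sd: 0.06
    visible_fraction: 0.6
  - name: stroma
    shape: ellipse
    count: 20
    semi_axes: [5, 15]
    mean_color: [0.20, 0.25, 0.70]
    color_sd: 0.06
    overlap: forbidden
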