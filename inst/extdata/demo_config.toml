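# Demonstration run configuration. Coordinates are 0-based; ROIs are
# half-open rectangles. Every stage draws from a substream of `seed`.
seed = 20260918

[stages]
photobleach = true
morphometry = true
omics = true
kinetics = true

[photobleach]
lattice_rows = 24
lattice_cols = 24
particles_per_site = 10
total_time = 80
frame_interval = 0.5
immobile_fraction_connected = 0.10
immobile_fraction_fragmented = 0.65
noise_sd = 0.02
n_replicates = 3
deplete_below = 0.25
preserve_above = 0.75

[morphometry]
n_cells = 60
inclusion_prevalence = 0.40
image_size = 128

[omics]
n_genes = 800
n_up = 40
n_down = 40
n_replicates = 5
n_a_exclusive = 14
n_b_exclusive = 3

[kinetics]
k_deg = 0.70
k_sec = 0.15
k_ret = 0.15
noise_sd = 0.02
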