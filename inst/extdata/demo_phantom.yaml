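layout: layered_biopsy
rows: 64
cols: 64
pixel_pitch: 6.25
snr: 500.0
thickness_range:
- 0.7
- 1.3
baseline_slope_sd: 2.0e-05
paraffin_residual: 0.0
boundary_mixing: yes
n_fibrosis: 2
n_foci: 3
focus_radius: 5.0
background_margin: 3
seed: 1
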