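# spherequant pipeline configuration template.
# Values below are the package defaults except the calibration block,
# whose numbers are PLACEHOLDERS: the true microns-per-pixel depends on
# your objective AND camera sensor. Measure it with a stage micrometer
# and replace before use.

# --- calibration (REQUIRED; placeholder values, not authoritative) ---
magnification = 10x
microns_per_pixel = 0.65

# --- preprocessing ---
clahe_clip_limit = 0.01
clahe_tile_grid = 8, 8
gaussian_sigma = 1.0

# --- Gabor texture bank ---
gabor_frequencies = 0.25, 0.166667, 0.125
gabor_orientations_deg = 0, 30, 60, 90, 120, 150
gabor_gamma = 10
gabor_eta = 0.5
gabor_kernel_size = 21

# --- region proposal / segmentation ---
roi_padding_px = 12
adaptive_block_fraction = 0.125
adaptive_offset = 0.02
struct_element_radius_px = 2
sphere_polarity = auto

# --- detection filters ---
min_sphere_area_um2 = 300
min_circularity = 0.4
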