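# Default scanner / binning / window configuration: one ring of 20 monolithic
# 50 x 50 x 20 mm blocks, inner faces 165 mm from the axis, 10% FWHM energy
# resolution at 511 keV, 350-650 keV acceptance, triple-energy-window layout.
n_blocks: 20
apothem_mm: 165.0
block_mm: [50.0, 50.0, 20.0]
axial_fov_mm: 60.0
transaxial_fov_mm: 330.0
energy_resolution_fwhm: 0.10
acceptance_window_kev: [350.0, 650.0]
min_block_sep: 5
pixel_pitch_mm: 2.0
window_mode: TEW
lew_upper_kev: 430.0
uew_lower_kev: 550.0
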