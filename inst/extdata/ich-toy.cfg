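# Example pipeline configuration: the default toy crystal at reduced
# resolution, quota supercell assignment, ensemble maps on.

[toy]
occ_closed     = 0.64
occ_closed_30s = 0.39
occ_reactive   = 0.85
occ_adduct     = 0.53
occ_water      = 0.64
adp_scale      = 15

[data]
dmin       = 2.0
noise_frac = 0.02

[supercell]
dims   = 2 2 2
frames = 3
seed   = 7
method = quota

[fits]
titration_pka = 5.7
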