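# Soft 1D double well: minima at +-3 A, 1 kB*T barrier at the origin,
# spring soft enough that ~100 A excursions cost ~1 kB*T.
form = double_well_1d
temperature = 300
param.k = 0.05
param.A = 249.6832422813
param.sig2 = 0.4872856251
box.1 = -150 150
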