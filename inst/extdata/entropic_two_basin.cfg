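# Entropic two-basin surface: isoenergetic basins at (+-1.3, 0) A behind a
# 3 kB*T barrier; y-widths 0.5 A (left) vs 50 A (right).
form = entropic_two_basin_2d
temperature = 300
param.h = 748.301634
param.x0 = 1.3
param.kapL = 997.735512
param.kapR = 0.0997735512
param.w = 0.2
box.1 = -4 4
box.2 = -200 200
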