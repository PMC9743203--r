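# Rotated/scaled quartic (Wolfe-Quapp family): two isoenergetic lower
# substates 30 A apart separated by 1.5 kB*T, upper basin behind 6.25 and
# 10 kB*T barriers from the left and right substates.
form = modified_wolfe_quapp_2d
temperature = 300
box.1 = -40 40
box.2 = -4 4
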