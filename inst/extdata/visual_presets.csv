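# Receptor-channel presets: one row per channel, ordered short->long lambda_max.
# eta = relative cone abundance; weber = Weber fraction of the most abundant
# channel; achromatic marks the double-cone (luminance) channel of bird
# systems. Butterfly presets carry no achromatic channel. Printed abundances
# and the erato UV/LW peak wavelengths follow the source measurements; the
# remaining peak wavelengths are package defaults and editable here.
preset,channel,lambda_max,eta,weber,achromatic
bluetit-uvs,UV,371,0.37,0.05,0
bluetit-uvs,SW,448,0.71,0.05,0
bluetit-uvs,MW,503,0.99,0.05,0
bluetit-uvs,LW,563,1,0.05,0
bluetit-uvs,D,563,1,0.05,1
peafowl-vs,V,432,0.45,0.05,0
peafowl-vs,SW,477,0.86,0.05,0
peafowl-vs,MW,537,1,0.05,0
peafowl-vs,LW,605,0.95,0.05,0
peafowl-vs,D,605,1,0.05,1
erato-female-green,UV1,355,0.086,0.05,0
erato-female-green,UV2,398,0.076,0.05,0
erato-female-green,B,470,0.17,0.05,0
erato-female-green,LW,555,1,0.05,0
erato-female-red,UV1,355,0.086,0.05,0
erato-female-red,UV2,398,0.076,0.05,0
erato-female-red,B,470,0.17,0.05,0
erato-female-red,LW,600,1,0.05,0
erato-male-green,UV2,398,0.13,0.05,0
erato-male-green,B,470,0.2,0.05,0
erato-male-green,LW,555,1,0.05,0
erato-male-red,UV2,398,0.13,0.05,0
erato-male-red,B,470,0.2,0.05,0
erato-male-red,LW,600,1,0.05,0
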