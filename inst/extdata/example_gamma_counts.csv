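subject,tissue,counts,injected_counts,tissue_weight_g
m01,BAT,18500,1000000,0.112
m01,eFat,2100,1000000,0.950
m01,sFat,2900,1000000,0.410
m01,muscle,1500,1000000,0.300
m02,BAT,26400,1050000,0.098
m02,eFat,1800,1050000,0.700
m02,sFat,3300,1050000,0.380
m02,muscle,1600,1050000,0.310
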