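gene,efficiency,r_squared
28S,94,0.997
Cycb,91,0.996
Daglb-2,98.4,0.995
Ebr1,90.1,1.000
GAPDH,105.2,0.991
Hmg1,101.9,0.999
Smtnl1,92,1.000
Ubb,92.5,0.999
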