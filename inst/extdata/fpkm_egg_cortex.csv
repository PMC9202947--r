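transcript,fpkm_egg,fpkm_cortex
Cycb,18086.99,15769.9
Daglb-2,2,9
Ebr1,7476.33,6490.31
Smtnl1,4183.87,3781.28
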