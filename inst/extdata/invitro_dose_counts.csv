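label,dose,r0,r1,r2,r3,printed_total,printed_lambda
1e10 vg/dish,1e10,14,77,184,1475,1750,7.9
5e10 vg/dish,5e10,5,9,52,1707,1773,12.4
5e11 vg/dish,5e11,0,0,0,1791,1791,NA
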