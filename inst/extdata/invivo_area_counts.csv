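label,dose,r0,r1,r2,r3,printed_total,printed_lambda
Anterior cingulate cortex,NA,0,0,20,3948,3968,19.2
Somatomotor cortex,NA,0,7,12,4319,4338,18.6
Prefrontal cortex,NA,0,3,13,4443,4459,19.7
Somatosensory cortex,NA,0,5,7,4712,4724,20.2
Cerebellar lobule VI,NA,0,4,15,4397,4316,19.0
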