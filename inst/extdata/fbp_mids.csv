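emu,mass_shift,fraction,sd,time
FBP[1-6],0,0.05,0.01,
FBP[1-6],2,0.833333333333333,0.01,
FBP[1-6],4,0.116666666666667,0.01,
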