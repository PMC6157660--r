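period,f,f_sd
MWP,0.88,0.02
LIA,0.37,0.3
all,0.8,0.4
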