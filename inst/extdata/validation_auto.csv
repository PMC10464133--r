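,PR,SD,PD
PR,4,2,0
SD,1,2,3
PD,2,0,17
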