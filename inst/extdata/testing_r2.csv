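,PR,SD,PD
PR,1,0,3
SD,3,3,5
PD,2,1,13
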