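,PR,SD,PD
PR,2,0,2
SD,3,3,1
PD,1,1,18
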