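,PR,SD,PD
PR,2,2,2
SD,4,2,2
PD,1,0,16
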