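,PR,SD,PD
PR,1,0,2
SD,4,3,3
PD,1,1,16
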