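,PR,SD,PD
PR,3,2,0
SD,3,2,1
PD,1,0,19
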