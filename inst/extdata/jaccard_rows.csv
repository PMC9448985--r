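,D1,D2,D3
L1,1,0,1
L2,1,1,0
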