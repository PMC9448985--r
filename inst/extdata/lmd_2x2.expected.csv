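0.50000000000000000,0.33333333333333331
0.33333333333333331,0.50000000000000000
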