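,D001,D002,D003,D004,D005,D006,D007,D008
M001,0,0,0,0,0,0,0,1
M002,0,0,0,0,0,0,0,0
M003,0,0,1,1,1,1,0,1
M004,0,0,0,1,0,0,0,1
M005,1,0,0,1,1,1,0,1
M006,0,0,0,0,0,0,0,1
M007,1,0,0,1,0,0,0,1
M008,0,0,0,0,0,0,0,1
M009,0,0,0,0,0,0,0,1
M010,0,0,0,0,0,0,0,1
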