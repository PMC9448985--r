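,M001,M002,M003,M004,M005,M006,M007,M008,M009,M010
L001,1,0,1,1,1,0,1,1,1,1
L002,0,0,1,0,1,0,0,0,0,0
L003,0,0,1,1,1,0,1,1,1,0
L004,0,0,0,0,0,0,0,0,0,0
L005,0,0,0,0,0,0,0,0,0,0
L006,0,0,1,0,1,1,0,0,1,0
L007,1,0,1,1,1,1,1,1,1,1
L008,0,0,0,0,0,0,0,0,0,0
L009,0,0,0,0,0,0,0,0,0,0
L010,0,0,0,0,0,0,0,0,0,0
L011,0,0,0,0,0,0,1,0,0,0
L012,0,0,0,0,0,0,0,0,0,0
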