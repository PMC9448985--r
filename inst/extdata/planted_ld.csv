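,D001,D002,D003,D004,D005,D006,D007,D008
L001,0,0,0,0,1,0,0,1
L002,0,0,0,0,0,0,0,1
L003,0,0,0,1,1,1,0,1
L004,0,0,0,0,0,0,0,0
L005,0,0,0,0,0,0,0,0
L006,0,0,0,0,0,0,0,1
L007,1,1,1,1,1,1,1,1
L008,0,0,0,0,0,0,0,1
L009,0,0,0,0,0,0,0,1
L010,0,0,0,0,0,0,0,0
L011,0,0,0,0,0,0,0,1
L012,0,0,0,0,0,0,0,0
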